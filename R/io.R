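# CSV input/output. Dialect: comma-separated, UTF-8, period decimal, header
# required, columns drug1.conc / drug2.conc / effect (optional sample),
# matching the common checkerboard upload format.

.as_dose_response <- function(x) {
  if (inherits(x, "dose_response")) return(x)
  stopifnot(is.data.frame(x))
  nm <- names(x)
  if (all(c("drug1.conc", "drug2.conc", "effect") %in% nm)) {
    x <- data.frame(d1 = x$drug1.conc, d2 = x$drug2.conc, effect = x$effect)
  }
  if (!all(c("d1", "d2", "effect") %in% names(x))) {
    stop("dose-response data needs columns d1, d2, effect ",
         "(or drug1.conc, drug2.conc, effect)", call. = FALSE)
  }
  stopifnot(is.numeric(x$d1), is.numeric(x$d2), is.numeric(x$effect))
  structure(x, class = unique(c("dose_response", class(x))))
}

#' Read checkerboard dose-response measurements from CSV
#'
#' Expects a header with columns `drug1.conc`, `drug2.conc`, `effect`
#' (an optional `sample` column tags replicates). Validation is strict and
#' each failure mode is a distinct error: missing file or empty body,
#' missing columns, non-numeric cells (reported with their line numbers),
#' and absence of monotherapy rows (both `drug2.conc == 0` and
#' `drug1.conc == 0` rows are required by the fitting pipeline). Rows with
#' non-finite values are dropped with a warning listing their line numbers.
#'
#' @param path Path to the CSV file.
#' @return A `dose_response` data frame with columns `d1`, `d2`, `effect`
#'   (and `sample` when present).
#' @export
read_dose_response_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  need <- c("drug1.conc", "drug2.conc", "effect")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("empty file: no data rows", call. = FALSE)
  # line number in the file = row index + header line
  lines <- seq_len(nrow(raw)) + 1L
  num <- lapply(raw[need], function(col) suppressWarnings(as.numeric(col)))
  for (col in need) {
    # a missing cell (empty or literal NA/NaN) is a non-finite row, handled
    # below; anything else that fails to parse is a hard validation error
    bad <- which(is.na(num[[col]]) & !is.na(raw[[col]]) &
                   !(raw[[col]] %in% c("NA", "NaN", "")))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value in column '%s' at line(s) %s",
                   col, paste(lines[bad], collapse = ", ")), call. = FALSE)
    }
  }
  out <- data.frame(d1 = num[["drug1.conc"]], d2 = num[["drug2.conc"]],
                    effect = num[["effect"]])
  if ("sample" %in% names(raw)) out$sample <- raw[["sample"]]
  drop <- !stats::complete.cases(out[c("d1", "d2", "effect")]) |
    !is.finite(out$d1) | !is.finite(out$d2) | !is.finite(out$effect)
  if (any(drop)) {
    warning("dropping ", sum(drop), " row(s) with non-finite values at ",
            "line(s) ", paste(lines[drop], collapse = ", "), call. = FALSE)
    out <- out[!drop, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("no usable rows after validation", call. = FALSE)
  if (any(out$d1 < 0) || any(out$d2 < 0)) {
    stop("negative concentrations are invalid", call. = FALSE)
  }
  if (!any(out$d2 == 0) || !any(out$d1 == 0)) {
    stop("no monotherapy rows: data must contain rows with drug2.conc == 0 ",
         "and rows with drug1.conc == 0", call. = FALSE)
  }
  rownames(out) <- NULL
  structure(out, class = c("dose_response", "data.frame"))
}

#' Write a dose-response table to CSV
#'
#' Inverse of [read_dose_response_csv()]; values round-trip exactly (written
#' with full precision).
#'
#' @param data A `dose_response` data frame (or anything coercible).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_response_csv <- function(data, path) {
  data <- .as_dose_response(data)
  out <- data.frame(drug1.conc = data$d1, drug2.conc = data$d2,
                    effect = data$effect, check.names = FALSE)
  if ("sample" %in% names(data)) out$sample <- data$sample
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write fitted surface parameters to CSV
#'
#' One row per fitted combination: every surface parameter with its
#' Monte-Carlo 95% bounds (`<name>`, `<name>.lower`, `<name>.upper`),
#' the derived synergy profile, goodness of fit, QC flag and reasons, and
#' the seed. QC-failed fits are written too, with empty parameter cells, so
#' a screen's output accounts for every combination.
#'
#' @param results A single `musyc_fit` or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_csv <- function(results, path) {
  if (inherits(results, "musyc_fit")) results <- list(results)
  stopifnot(is.list(results))
  par_names <- c("E0", "E1", "E2", "E3", "C1", "C2", "h1", "h2",
                 "log10_alpha12", "log10_alpha21",
                 "log10_gamma12", "log10_gamma21", "beta")
  cols <- c("combination", "r_squared", "rms", "qc_pass", "qc_reasons",
            "seed",
            unlist(lapply(par_names,
                          function(p) c(p, paste0(p, ".lower"),
                                        paste0(p, ".upper")))))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    stopifnot(inherits(r, "musyc_fit"))
    row <- stats::setNames(as.list(rep(NA_real_, length(cols))), cols)
    row$combination <- if (!is.null(names(results)[i]) &&
                           nzchar(names(results)[i])) {
      names(results)[i]
    } else {
      as.character(i)
    }
    row$r_squared <- r$r_squared
    row$rms <- r$rms
    row$qc_pass <- isTRUE(r$qc_pass)
    row$qc_reasons <- paste(r$qc_reasons, collapse = "; ")
    row$seed <- if (is.null(r$seed)) NA_integer_ else r$seed
    if (!is.null(r$ci)) {
      for (j in seq_len(nrow(r$ci))) {
        p <- r$ci$parameter[j]
        if (p %in% par_names) {
          row[[p]] <- r$ci$estimate[j]
          row[[paste0(p, ".lower")]] <- r$ci$lower[j]
          row[[paste0(p, ".upper")]] <- r$ci$upper[j]
        }
      }
    }
    as.data.frame(row, check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))),
                    cols)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a fitting configuration from YAML
#'
#' Recognized keys mirror [fit_config()] arguments: `e0_bounds`,
#' `e1_bounds`, `e2_bounds`, `e3_bounds` (2-element lists), `orientation`,
#' `gamma_enabled`, `log_alpha_bounds`, `mc_samples`, `seed`,
#' `r2_threshold`, `stage1_se_mult`. Missing keys take the defaults;
#' unknown keys are an error (they are usually typos).
#'
#' @param path Path to a YAML file.
#' @return A [fit_config()].
#' @export
read_fit_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- names(formals(fit_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  y <- lapply(y, function(v) if (is.list(v)) unlist(v) else v)
  do.call(fit_config, y)
}
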