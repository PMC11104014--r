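#' Read per-run fit rows from CSV
#'
#' Comma-separated, dot-decimal, mandatory header. Unicode minus signs
#' (U+2212), as found in typeset tables, are normalized to ASCII hyphens
#' on input.
#'
#' @param path CSV path with columns `m_R1`, `b_R1`, `r_R1`, `m_R2`,
#'   `b_R2`, `r_R2` and optionally `table`, `run`.
#' @return Data frame of numeric columns.
#' @export
read_fit_rows_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- gsub("−", "-", lines)
  utils::read.csv(text = lines, stringsAsFactors = FALSE)
}

#' Read size-versus-rate pairs from CSV
#'
#' Two-column CSV with header `size,rate` (extra columns are ignored).
#'
#' @param path CSV path.
#' @return Data frame with columns `size`, `rate`.
#' @export
read_size_rate_csv <- function(path) {
  d <- read_fit_rows_csv(path)
  if (!all(c("size", "rate") %in% names(d)))
    stop("expected header columns `size` and `rate` in ", path,
         call. = FALSE)
  d[c("size", "rate")]
}

#' Write per-radius summaries with the relative curve
#'
#' Emits one row per radius with columns `radius`, `mean_steps`,
#' `sd_steps`, `n`, `relative_percent`, plus a plain-text key-value
#' metadata sidecar (`<path>.meta`) recording the experiment spec.
#'
#' @param experiment An [run_experiment()] result.
#' @param path Output CSV path.
#' @param force Passed to [relative_curve()].
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(experiment, path, force = FALSE) {
  rel <- relative_curve(experiment, force = force)
  out <- data.frame(radius = experiment$radius,
                    mean_steps = experiment$mean_steps,
                    sd_steps = experiment$sd_steps,
                    n = experiment$n,
                    relative_percent = rel$relative_percent)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  spec <- attr(experiment, "spec")
  if (!is.null(spec)) {
    cfg <- spec[c("edge_length", "repeats", "master_seed",
                  "reference_radius", "run_index", "start_mode",
                  "max_steps", "boundary_policy")]
    cfg$radii <- paste(spec$radii, collapse = " ")
    cfg$package_version <-
      as.character(utils::packageVersion("phagewalk"))
    write_run_config(cfg, paste0(path, ".meta"))
  }
  invisible(path)
}

#' Read a relative curve from a summary CSV
#'
#' @param path CSV written by [write_summary_csv()] (columns `radius`,
#'   `relative_percent` required; `mean_steps` kept when present).
#' @param reference_radius Reference radius recorded on the curve; when
#'   `NULL`, inferred as the radius whose relative value is 100.
#' @return A `relative_curve` data frame.
#' @export
read_curve_csv <- function(path, reference_radius = NULL) {
  d <- read_fit_rows_csv(path)
  if (!all(c("radius", "relative_percent") %in% names(d)))
    stop("expected columns `radius` and `relative_percent` in ", path,
         call. = FALSE)
  if (is.null(reference_radius)) {
    i <- which(abs(d$relative_percent - 100) < 1e-9)
    if (length(i) != 1L)
      stop("cannot infer reference radius from ", path, call. = FALSE)
    reference_radius <- d$radius[i]
  }
  out <- d[intersect(c("radius", "mean_steps", "relative_percent"),
                     names(d))]
  attr(out, "reference_radius") <- reference_radius
  class(out) <- c("relative_curve", "data.frame")
  out
}

#' Write a comparison table as CSV
#'
#' Per-run rows followed by `Means`, `SDs` and `p-values` trailing rows —
#' the published table layout. Inapplicable cells (single run, or p-values
#' for the second exponent's columns) are emitted as `NA`.
#'
#' @param fit An [encounter_fit()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(fit, path) {
  tab <- comparison_table(fit)
  stat_cols <- setdiff(names(tab$rows), "run")
  fmt <- function(v) ifelse(is.na(v), "NA", format(v, digits = 10))
  rows <- cbind(run = as.character(tab$rows$run),
                vapply(tab$rows[stat_cols], fmt,
                       character(nrow(tab$rows))))
  pv <- rep(NA_real_, length(stat_cols))
  names(pv) <- stat_cols
  pv[seq_len(min(3, length(stat_cols)))] <- tab$p_values[seq_len(3)]
  sumr <- rbind(c("Means", fmt(tab$means)),
                c("SDs", fmt(tab$sds)),
                c("p-values", fmt(pv)))
  out <- rbind(rows, sumr)
  colnames(out) <- c("run", stat_cols)
  utils::write.csv(as.data.frame(out), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Flat key-value run configuration files
#'
#' `key = value` lines, one per key; blank lines and `#` comments ignored.
#' Loading then saving then loading reproduces the configuration exactly;
#' unknown keys are rejected loudly by [cli_main()] validation.
#'
#' @param path Config file path.
#' @return Named list of character values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(m, length, 0L) != 3L]
  if (length(bad))
    stop("malformed config line(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  stats::setNames(lapply(m, function(x) trimws(x[3])),
                  vapply(m, `[[`, "", 2))
}

#' @rdname read_run_config
#' @param config Named list of scalar values.
#' @export
write_run_config <- function(config, path) {
  stopifnot(!is.null(names(config)), all(nzchar(names(config))))
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) paste(format(v), collapse = " "),
                            "")),
             path)
  invisible(path)
}
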