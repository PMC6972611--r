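# Plain-text readers/writers for the tabular interchange formats: partition
# integral tables, PFG-STE decay tables (with `# key: value` metadata
# headers), relaxation tables, NOESY intensity tables and titration logs.

check_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("malformed table %s: missing column(s) %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

read_metadata_header <- function(path) {
  lines <- readLines(path, n = 50)
  meta_lines <- grep("^#", lines, value = TRUE)
  out <- list()
  for (l in meta_lines) {
    m <- regmatches(l, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*[:=]\\s*(.+)$", l))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      out[[m[2]]] <- if (is.na(val)) trimws(m[3]) else val
    }
  }
  out
}

#' Read a partition peak-integral table
#'
#' Accepts either raw columns `pH, I_a, I_a_star` or pre-reduced columns
#' `n_star_mM, c_IbuH_L1_mM`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_partition_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("n_star_mM", "c_IbuH_L1_mM") %in% names(df)))
    check_columns(df, c("pH", "I_a", "I_a_star"), path)
  df
}

#' Read a PFG-STE decay table
#'
#' Expects columns `g_T_per_m, intensity` with metadata header lines
#' `# delta_s: ...`, `# Delta_s: ...`, `# gamma: ...` (and optionally
#' `# phase: ...`), or alternatively precomputed `b_s_per_m2, intensity`.
#'
#' @param path CSV path.
#' @return A [decay_curve()].
#' @export
read_decay_table <- function(path) {
  meta <- read_metadata_header(path)
  df <- utils::read.csv(path, comment.char = "#")
  check_columns(df, "intensity", path)
  if (any(!is.finite(df$intensity)) || any(df$intensity <= 0))
    stop(sprintf("malformed table %s: column intensity must be positive", path),
         call. = FALSE)
  phase <- if (!is.null(meta$phase)) meta$phase else "mother"
  if ("b_s_per_m2" %in% names(df))
    return(decay_curve(b = df$b_s_per_m2, intensity = df$intensity,
                       phase = phase))
  check_columns(df, "g_T_per_m", path)
  for (k in c("delta_s", "Delta_s"))
    if (is.null(meta[[k]]))
      stop(sprintf("decay table %s lacks metadata header `# %s: ...`", path, k),
           call. = FALSE)
  decay_curve(g = df$g_T_per_m, intensity = df$intensity,
              delta_s = meta$delta_s, Delta_s = meta$Delta_s,
              gamma = if (is.null(meta$gamma)) GAMMA_1H else meta$gamma,
              phase = phase)
}

#' Write a decay curve as a CSV with metadata header
#'
#' @param curve A [decay_curve()].
#' @param path Output path.
#' @export
write_decay_table <- function(curve, path) {
  stopifnot(inherits(curve, "decay_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# delta_s: %.10g", curve$delta_s), con)
  writeLines(sprintf("# Delta_s: %.10g", curve$Delta_s), con)
  writeLines(sprintf("# gamma: %.10g", curve$gamma), con)
  writeLines(sprintf("# phase: %s", curve$phase), con)
  df <- if (is.null(curve$g))
    data.frame(b_s_per_m2 = curve$b, intensity = curve$intensity)
  else
    data.frame(g_T_per_m = curve$g, intensity = curve$intensity)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a relaxation table (`peak, T1_s, T2_s`)
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_relaxation_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  check_columns(df, c("peak", "T1_s", "T2_s"), path)
  if (any(df$T2_s <= 0) || any(df$T1_s < df$T2_s))
    stop(sprintf("malformed table %s: need T1_s >= T2_s > 0", path),
         call. = FALSE)
  df
}

#' Read a NOESY intensity table (`pair, intensity, is_reference`)
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_noesy_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  check_columns(df, c("pair", "intensity", "is_reference"), path)
  df$is_reference <- as.logical(df$is_reference)
  df
}

#' Read a titration log (`time_s, v_hcl_mL, v_ibuna_mL[, pH]`)
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_titration_log <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  check_columns(df, c("time_s", "v_hcl_mL", "v_ibuna_mL"), path)
  df
}
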