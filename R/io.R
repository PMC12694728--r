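# Plain-text formats: trace CSV with JSON sidecar, I-V tables, Cm-V tables,
# and JSON fit records.

#' Write a sweep set as trace CSV plus JSON sidecar
#'
#' The trace file has columns `sweep_id,t_ms,V_mV,I_pA,light`
#' (light in none/uv/blue) with a mandatory header row; the sidecar
#' `<prefix>.json` records protocol, kinetics, noise/filter spec, seed and
#' condition labels.
#'
#' @param sweeps A `sweep_set`.
#' @param prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return The CSV path, invisibly.
#' @export
write_traces <- function(sweeps, prefix) {
  stopifnot(inherits(sweeps, "sweep_set"))
  csv <- paste0(prefix, ".csv")
  utils::write.csv(as.data.frame(sweeps$traces), csv, row.names = FALSE,
                   quote = FALSE)
  meta <- list(protocol = unclass(sweeps$protocol),
               light = if (!is.null(sweeps$light)) unclass(sweeps$light),
               kinetics = if (!is.null(sweeps$kinetics)) unclass(sweeps$kinetics),
               noise_filter = if (!is.null(sweeps$nf)) unclass(sweeps$nf),
               seed = sweeps$seed,
               conditions = sweeps$conditions)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(csv)
}

#' Read a trace CSV (and sidecar) into a sweep set
#'
#' Validates the schema (required columns, strictly increasing time and a
#' common sampling grid within each sweep) and normalizes sweep order, so
#' files with shuffled sweep blocks load identically.
#'
#' @param path Path to the trace CSV; a sidecar `.json` next to it is read
#'   when present.
#' @return A `sweep_set`.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sweep_id", "t_ms", "V_mV", "I_pA", "light")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop_pc("trace file %s is missing column(s): %s", path,
            paste(missing_cols, collapse = ", "))
  bad <- which(!df$light %in% c("none", "uv", "blue"))
  if (length(bad) > 0)
    stop_pc("invalid light annotation %s at data row %d of %s",
            df$light[bad[1]], bad[1], path)
  ids <- unique(df$sweep_id)
  grids <- list()
  for (id in ids) {
    t <- df$t_ms[df$sweep_id == id]
    if (any(diff(t) <= 0))
      stop_pc("time is not strictly increasing within sweep %s of %s", id, path)
    grids[[id]] <- t
  }
  n_samp <- lengths(grids)
  if (length(unique(n_samp)) != 1L ||
      !all(vapply(grids, function(g) isTRUE(all.equal(g, grids[[1]])), logical(1))))
    stop_pc("sweeps in %s do not share a common sampling grid", path)
  # canonical order: locale-independent sort of sweep ids, time within sweep
  df <- df[order(match(df$sweep_id, sort(ids, method = "radix")), df$t_ms), ,
           drop = FALSE]
  rownames(df) <- NULL
  for (col in c("t_ms", "V_mV", "I_pA")) df[[col]] <- as.numeric(df[[col]])
  traces <- tibble::as_tibble(df)

  sidecar <- sub("\\.csv$", ".json", path)
  proto <- NULL; light <- NULL; kin <- NULL; nf <- NULL; seed <- NULL; cond <- list()
  if (file.exists(sidecar) && sidecar != path) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$protocol))
      proto <- do.call(step_protocol, with(meta$protocol, list(
        hold_mV = hold_mV, hold_ms = hold_ms,
        v_start_mV = step_levels_mV[1],
        v_stop_mV = step_levels_mV[length(step_levels_mV)],
        v_step_mV = if (length(step_levels_mV) > 1)
          step_levels_mV[2] - step_levels_mV[1] else -20,
        sweep_ms = sweep_ms, dt_ms = dt_ms, inter_sweep_s = inter_sweep_s)))
    if (!is.null(meta$light))
      light <- light_protocol(meta$light$uv_ms, meta$light$blue_ms,
                              meta$light$uv_irradiance %||% 1,
                              meta$light$blue_irradiance %||% 1)
    if (!is.null(meta$kinetics)) kin <- do.call(photoswitch_kinetics, meta$kinetics)
    if (!is.null(meta$noise_filter)) {
      nfm <- meta$noise_filter
      nf <- noise_filter_spec(nfm$noise_sd_pA %||% 0, nfm$filter_cutoff_kHz,
                              nfm$filter_order %||% 4L,
                              nfm$series_resistance_MOhm %||% 0,
                              nfm$membrane_capacitance_pF %||% 0)
    }
    seed <- meta$seed
    cond <- as.list(meta$conditions %||% list())
  }
  new_sweep_set(traces, proto, light, kin, nf, seed, cond)
}

#' Write an I-V table
#'
#' Delimited text with columns `V_mV,I_pA` and, when present, `SD_pA,n`.
#'
#' @param iv An `iv_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_iv_table <- function(iv, path) {
  utils::write.csv(as.data.frame(iv), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an I-V table written by [write_iv_table()]
#' @param path Input path.
#' @return An `iv_curve`.
#' @export
read_iv_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("V_mV", "I_pA") %in% names(df)))
    stop_pc("I-V table %s needs columns V_mV, I_pA", path)
  iv_curve(df$V_mV, df$I_pA, SD_pA = df$SD_pA, n = df$n)
}

#' Write / read a Cm-V table (`V_mV,C`)
#' @param cmv A `cmv_curve`.
#' @param path File path.
#' @return `path` (write) or a `cmv_curve` (read), invisibly for write.
#' @export
write_cmv_table <- function(cmv, path) {
  utils::write.csv(as.data.frame(cmv), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cmv_table
#' @export
read_cmv_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("V_mV", "C") %in% names(df)))
    stop_pc("Cm-V table %s needs columns V_mV, C", path)
  cmv_curve(df$V_mV, df$C)
}

#' Serialize a fit object as a JSON record
#'
#' Writes any of the package's fit objects (`iv_fit`, `biexp_fit`,
#' `transient_fit`, `parabola_fit`, ...) as JSON with full precision.
#'
#' @param fit A fit object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  x <- unclass(fit)
  x$fit_class <- class(fit)[1]
  x <- lapply(x, function(el) {
    if (inherits(el, "data.frame")) as.list(el)
    else if (is.matrix(el)) list(values = as.vector(el), dim = dim(el))
    else el
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
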