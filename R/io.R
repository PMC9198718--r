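#' Write a recording as a plain sweep table
#'
#' Long-format CSV dialect for raw sweep sets, also accepted as the real-data
#' entry point: columns `cell_id`, `sweep_type` (`"test"` or `"p8"`),
#' `v_mV` (test voltage label of the sweep), `rep` (subpulse index; 0 for
#' test sweeps), `t_ms` (time within sweep) and `i_pA`.
#'
#' @param rec A `clc_recording`.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_sweep_table <- function(rec, file) {
  stopifnot(inherits(rec, "clc_recording"))
  seg <- protocol_segments(rec$protocol)
  volts <- protocol_voltages(rec$protocol)
  t_all <- (seq_len(seg$n_total) - 1) * seg$dt
  test <- data.frame(
    cell_id = rec$meta$cell_id, sweep_type = "test",
    v_mV = rep(volts, each = seg$n_total), rep = 0L,
    t_ms = rep(t_all, length(volts)), i_pA = as.vector(rec$sweeps))
  p8 <- data.frame(
    cell_id = rec$meta$cell_id, sweep_type = "p8",
    v_mV = rep(volts, each = seg$n_total * dim(rec$p8)[2]),
    rep = rep(rep(seq_len(dim(rec$p8)[2]), each = seg$n_total),
              length(volts)),
    t_ms = rep(t_all, dim(rec$p8)[2] * length(volts)),
    i_pA = as.vector(rec$p8))
  utils::write.csv(rbind(test, p8), file, row.names = FALSE)
  invisible(file)
}

#' Read a sweep table into a recording
#'
#' @param file CSV in the [write_sweep_table()] dialect (test sweeps alone
#'   are accepted; P/8 sweeps are required for [p8_subtract()]).
#' @param protocol The [protocol_spec()] the sweeps were acquired under.
#' @param fluorescence Whole-cell fluorescence (a.u.), if known.
#' @param variant Optional [variant_config()] metadata.
#' @return A `clc_recording`.
#' @export
read_sweep_table <- function(file, protocol, fluorescence = NA_real_,
                             variant = NULL) {
  d <- utils::read.csv(file)
  need <- c("cell_id", "v_mV", "t_ms", "i_pA")
  if (!all(need %in% names(d)))
    stop("sweep table must have columns ", paste(need, collapse = ", "))
  if (is.null(d$sweep_type)) d$sweep_type <- "test"
  if (is.null(d$rep)) d$rep <- 0L
  seg <- protocol_segments(protocol)
  volts <- protocol_voltages(protocol)

  test <- d[d$sweep_type == "test", ]
  test <- test[order(match(test$v_mV, volts), test$t_ms), ]
  if (nrow(test) != seg$n_total * length(volts))
    stop("test sweeps do not match the protocol (samples x voltages)")
  sweeps <- matrix(test$i_pA, seg$n_total, length(volts))

  p8d <- d[d$sweep_type == "p8", ]
  if (nrow(p8d) > 0) {
    n_rep <- max(p8d$rep)
    p8d <- p8d[order(match(p8d$v_mV, volts), p8d$rep, p8d$t_ms), ]
    if (nrow(p8d) != seg$n_total * n_rep * length(volts))
      stop("P/8 sweeps do not match the protocol")
    p8 <- array(p8d$i_pA, c(seg$n_total, n_rep, length(volts)))
  } else {
    p8 <- array(0, c(seg$n_total, 0, length(volts)))
  }
  dv <- volts - protocol$holding
  if (is.null(variant))
    variant <- variant_config(as.character(d$cell_id[1]), v_half = NA)
  structure(list(protocol = protocol, variant = variant,
                 passive = NULL, sweeps = sweeps, p8 = p8,
                 p8_amp = -abs(dv) / protocol$p8_count,
                 fluorescence = fluorescence, components = NULL,
                 truth = NULL,
                 meta = list(cell_id = as.character(d$cell_id[1]),
                             variant = variant$name, seed = NA),
                 subtracted = FALSE), class = "clc_recording")
}

#' Write a simulated cohort to a directory
#'
#' Emits `manifest.csv` (per-cell metadata and ground truth),
#' `protocol.json`, `ground_truth.json` and one sweep-table CSV per cell.
#' Note that full-resolution sweep tables are large; this format is intended
#' for interchange of small cohorts.
#'
#' @param cohort A `clc_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "clc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(cohort$protocol),
                       file.path(dir, "protocol.json"), auto_unbox = TRUE)
  jsonlite::write_json(lapply(cohort$cells, `[[`, "truth"),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  for (rec in cohort$cells)
    write_sweep_table(rec, file.path(dir, paste0(rec$meta$cell_id, ".csv")))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort_csv()]
#' @param dir Cohort directory.
#' @return A `clc_cohort` (ground truth reattached from the JSON sidecar).
#' @export
read_cohort_csv <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  pj <- jsonlite::read_json(file.path(dir, "protocol.json"),
                            simplifyVector = TRUE)
  protocol <- do.call(protocol_spec, pj[setdiff(names(pj), character())])
  truths <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                simplifyVector = TRUE)
  cells <- lapply(seq_len(nrow(man)), function(i) {
    rec <- read_sweep_table(file.path(dir, paste0(man$cell_id[i], ".csv")),
                            protocol, fluorescence = man$fluorescence[i])
    rec$meta$variant <- man$variant[i]
    rec$truth <- truths[[man$cell_id[i]]]
    rec$variant$name <- man$variant[i]
    rec$variant$v_ref <- man$v_ref[i]
    rec
  })
  names(cells) <- man$cell_id
  structure(list(cells = cells, manifest = man, protocol = protocol,
                 passive = NULL, seed = NA), class = "clc_cohort")
}

#' Write / read a two-channel image pair as multi-channel TIFF
#'
#' Intensities are stored as 32-bit floats scaled by `scale` (default: left
#' as-is divided by `scale`); ground-truth channels are not persisted.
#'
#' @param pair An `image_pair` (or list with `ch1`, `ch2`).
#' @param file TIFF path.
#' @param scale Intensity divisor applied before writing (TIFF float
#'   channels conventionally hold values in the unit range).
#' @return `file` invisibly; `read_image_pair()` returns a list with `ch1`,
#'   `ch2` on the original scale.
#' @export
write_image_pair <- function(pair, file, scale = 2^16) {
  tiff::writeTIFF(list(pair$ch1 / scale, pair$ch2 / scale), file,
                  bits.per.sample = 32, reduce = FALSE)
  invisible(file)
}

#' @rdname write_image_pair
#' @export
read_image_pair <- function(file, scale = 2^16) {
  imgs <- tiff::readTIFF(file, all = TRUE)
  if (length(imgs) < 2) stop("expected a two-channel TIFF")
  list(ch1 = imgs[[1]] * scale, ch2 = imgs[[2]] * scale)
}

#' Write / read a gel lane profile as CSV plus JSON sidecar
#'
#' The CSV holds two columns (`position`, `intensity`); the sidecar stores
#' the MW calibration map and any band annotations.
#'
#' @param lane A `lane_profile`.
#' @param file CSV path; the sidecar is `<file>.json`.
#' @return `file` invisibly; `read_lane_csv()` returns a `lane_profile`.
#' @export
write_lane_csv <- function(lane, file) {
  stopifnot(inherits(lane, "lane_profile"))
  utils::write.csv(data.frame(position = lane$position,
                              intensity = lane$intensity),
                   file, row.names = FALSE)
  jsonlite::write_json(list(mw_map = lane$mw_map, bands = lane$bands),
                       paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_lane_csv
#' @export
read_lane_csv <- function(file) {
  d <- utils::read.csv(file)
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  bands <- side$bands
  if (!is.null(bands) && !is.data.frame(bands))
    bands <- as.data.frame(bands)
  lane_profile(d$position, d$intensity, side$mw_map, bands)
}
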