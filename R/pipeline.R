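#' Default end-to-end pipeline configuration
#'
#' Runs the full simulated study design: the 12-variant panel plus WT (and
#' the linker chimeras) through the electrophysiology pipeline with the
#' study's activation-analysis cohort sizes, a colocalization cohort
#' calibrated to the designed WT/ClC-3b overlap level, a demonstration
#' glycosylation lane and native-gel lane, and the assumption-gated group
#' statistics.
#'
#' @param n_default Cohort size for variants without a published
#'   activation-analysis n.
#' @return A nested configuration list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(n_default = 6) {
  list(
    ephys = list(enabled = TRUE, variant_set = "both",
                 n_cells = NULL, n_default = n_default,
                 protocol = list(), passive = list()),
    coloc = list(enabled = TRUE, n_images = 11, target_overlap = 0.83),
    gel = list(enabled = TRUE),
    stats = list(enabled = TRUE, reference = "WT",
                 metrics = c("v_half", "rho", "i_ss_max")))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> trace processing -> transport metrics ->
#' colocalization -> densitometry -> statistics according to a configuration
#' list (or YAML/JSON file path). Stages run independently: disabled stages
#' are skipped without error. Outputs are written as tidy CSV tables plus a
#' JSON report; the run is fully deterministic given `config` and `seed`.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML/JSON file with the same structure.
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Output directory, created if needed; `NULL` skips file
#'   output.
#' @return List with elements `metrics` (per-cell), `summary` (per-variant),
#'   `coloc`, `gel`, `stats`, `log`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = 1,
                         out_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("[.]ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  log <- c(sprintf("clc4quant pipeline, seed %d", seed),
           sprintf("R %s", getRversion()))
  out <- list(metrics = NULL, summary = NULL, coloc = NULL, gel = NULL,
              stats = NULL)

  ce <- config$ephys
  if (isTRUE(ce$enabled)) {
    variants <- if (!is.null(ce$variants)) ce$variants
                else clc4_variants(ce$variant_set %||% "both")
    n_qv <- attr(variants, "n_qv")
    n_cells <- ce$n_cells
    if (is.null(n_cells)) {
      n_cells <- if (!is.null(n_qv)) {
        n <- n_qv[vapply(variants, `[[`, "", "name")]
        n[is.na(n)] <- ce$n_default %||% 6
        as.integer(n)
      } else ce$n_default %||% 6
    }
    protocol <- do.call(protocol_spec, ce$protocol %||% list())
    passive <- do.call(cell_passive_spec, ce$passive %||% list())
    cohort <- simulate_cohort(variants, n_cells, protocol, passive,
                              seed = seed)
    an <- analyze_cohort(cohort)
    out$metrics <- an$metrics
    out$summary <- an$summary
    log <- c(log, sprintf("ephys: %d cells across %d variants",
                          nrow(an$metrics), length(variants)))
  }

  cc <- config$coloc
  if (isTRUE(cc$enabled)) {
    spec <- do.call(image_synth_spec, cc$spec %||% list())
    if (!is.null(cc$target_overlap))
      spec <- calibrate_overlap(cc$target_overlap, spec,
                                seed = seed + 1000L)
    n_img <- cc$n_images %||% 11
    rows <- lapply(seq_len(n_img), function(i) {
      pair <- synth_image_pair(spec, seed = seed + 2000L + i)
      res <- manders_overlap(pair, threshold_channels(pair))
      data.frame(image = i, overlap = res$overlap_coefficient,
                 m1 = res$m1, m2 = res$m2,
                 overlap_prob = spec$overlap_prob)
    })
    out$coloc <- do.call(rbind, rows)
    log <- c(log, sprintf(
      "coloc: %d images, overlap_prob %.3f, mean R %.3f", n_img,
      spec$overlap_prob, mean(out$coloc$overlap)))
  }

  cg <- config$gel
  if (isTRUE(cg$enabled)) {
    out$gel <- gel_demo_results(seed = seed + 3000L)
    log <- c(log, sprintf("gel: glycosylated fraction %.3f, heterodimer fraction %.3f",
                          out$gel$fraction[out$gel$quantity == "glycosylated_fraction"],
                          out$gel$fraction[out$gel$quantity == "heterodimer_fraction"]))
  }

  cs <- config$stats
  if (isTRUE(cs$enabled) && !is.null(out$metrics)) {
    ref <- cs$reference %||% "WT"
    out$stats <- lapply(stats::setNames(nm = cs$metrics), function(m) {
      vals <- out$metrics[[m]]
      if (m == "rho") vals[!out$metrics$rho_defined] <- NA
      tryCatch(compare_groups(vals, out$metrics$variant, reference = ref),
               error = function(e) NULL)
    })
    branches <- vapply(out$stats,
                       function(s) if (is.null(s)) "skipped" else s$method, "")
    log <- c(log, paste0("stats gate branches: ",
                         paste(names(branches), branches, sep = "=",
                               collapse = ", ")))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(out$metrics))
      utils::write.csv(out$metrics,
                       file.path(out_dir, "per_cell_metrics.csv"),
                       row.names = FALSE)
    if (!is.null(out$summary))
      utils::write.csv(out$summary,
                       file.path(out_dir, "variant_summary.csv"),
                       row.names = FALSE)
    if (!is.null(out$coloc))
      utils::write.csv(out$coloc, file.path(out_dir, "coloc_results.csv"),
                       row.names = FALSE)
    if (!is.null(out$gel))
      utils::write.csv(out$gel, file.path(out_dir, "gel_results.csv"),
                       row.names = FALSE)
    if (!is.null(out$stats)) {
      pw <- do.call(rbind, lapply(names(out$stats), function(m) {
        s <- out$stats[[m]]
        if (is.null(s)) return(NULL)
        cbind(metric = m, method = s$method, s$pairwise)
      }))
      if (!is.null(pw))
        utils::write.csv(pw, file.path(out_dir, "stats_pairwise.csv"),
                         row.names = FALSE)
    }
    jsonlite::write_json(
      list(seed = seed, log = log,
           summary = out$summary, coloc_mean = if (!is.null(out$coloc))
             mean(out$coloc$overlap) else NULL),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    writeLines(log, file.path(out_dir, "log.txt"))
  }
  out$log <- log
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# demonstration gel quantification on synthetic lanes with designed
# proportions (glycosylated fraction 0.25; heterodimer fraction 1/3)
gel_demo_results <- function(seed = 1) {
  glyc_lane <- synth_gel_lane(gel_lane_spec(data.frame(
    label = c("glycosylated", "core"), mw_kda = c(120, 100),
    area = c(25, 75), width = c(1.5, 1.2))), seed = seed)
  q <- quantify_roi(glyc_lane, 80, 140)
  gf <- glycosylation_fraction(q$per_band[["glycosylated"]],
                               q$per_band[["core"]])

  # native-gel lane: monomers, homodimers and the two heterodimer bands are
  # individually resolvable, as on the real gel where species are assigned
  # by eye from co/single-transfection lanes
  hr_lane <- synth_gel_lane(gel_lane_spec(data.frame(
    label = c("clc3_monomer", "clc4_monomer", "clc4_homodimer",
              "heterodimer_1", "heterodimer_2", "clc3_homodimer"),
    mw_kda = c(145, 130, 205, 237, 273, 316),
    area = c(30, 30, 5, 20, 15, 15),
    width = c(0.6, 0.6, 0.8, 0.8, 0.8, 0.8)),
    migration_a = 230, migration_b = 80), seed = seed + 1)
  # baseline window wider than the dimer band cluster so the opening
  # returns to the true baseline between bands
  qh <- quantify_roi(hr_lane, 100, 400, baseline_window = 30)
  hf <- heterodimer_fraction(qh$per_band)

  rbind(
    data.frame(quantity = "glycosylated_fraction", fraction = gf$fraction,
               designed = 0.25),
    data.frame(quantity = "heterodimer_fraction", fraction = hf$fraction,
               designed = 35 / 115))
}

#' Evaluate recovery targets against pipeline results
#'
#' Compares computed cohort-level values with their configured design values
#' (the simulator's ground truth) and reports machine-readable verdicts.
#' The default target table checks per-variant mean fitted V0.5 against the
#' configured activation midpoints (tolerance 3 mV) and mean recovered
#' Q_off/current ratio against the designed `rho_ref` (tolerance 10%).
#'
#' @param summary Per-variant summary from [analyze_cohort()] /
#'   [run_pipeline()].
#' @param targets Data frame with columns `metric`, `variant`, `target`,
#'   `tolerance`; `NULL` builds the default table from the variant panel.
#' @param file Optional JSON output path.
#' @return Data frame of verdicts: metric, variant, value, target,
#'   tolerance, pass (or `NA` when not evaluable).
#' @export
acceptance_report <- function(summary, targets = NULL, file = NULL) {
  if (is.null(targets)) {
    panel <- clc4_variants("both")
    n_qv <- attr(panel, "n_qv")
    known <- names(n_qv)[!is.na(n_qv)]
    targets <- rbind(
      data.frame(metric = "v_half_mean", variant = known,
                 target = vapply(panel[known], `[[`, 0, "v_half"),
                 tolerance = 3),
      data.frame(metric = "rho_mean", variant = known,
                 target = vapply(panel[known], `[[`, 0, "rho_ref"),
                 tolerance = 0.1 * vapply(panel[known], `[[`, 0, "rho_ref")))
  }
  verdicts <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, ]
    row <- summary[summary$variant == tg$variant, ]
    value <- if (nrow(row) == 1 && tg$metric %in% names(row))
      row[[tg$metric]] else NA_real_
    data.frame(metric = tg$metric, variant = tg$variant, value = value,
               target = tg$target, tolerance = tg$tolerance,
               pass = if (is.na(value)) NA
                      else abs(value - tg$target) <= tg$tolerance)
  }))
  rownames(verdicts) <- NULL
  if (!is.null(file))
    jsonlite::write_json(verdicts, file, auto_unbox = TRUE, digits = NA)
  verdicts
}
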