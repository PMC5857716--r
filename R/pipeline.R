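# Orchestration of the two analysis tracks, with optional on-disk reports
# and a run manifest for provenance.

#' Run the identity-decay track end to end
#'
#' Takes an identity table (observed pairwise identities with optional
#' fossil ages), calibrates a decay rate for each assumed MRCA age,
#' extrapolates the duplication age implied by the between-paralogue
#' identity, checks every fossil-dated record against the baseline rate,
#' and assembles the decay-curve data (identity against age with
#' uncertainty bars). If `out_dir` is given, all tables are written as TSV
#' alongside a JSON manifest; outputs are deterministic, so regenerating a
#' report from the same inputs is byte-identical.
#'
#' @param identity An identity tibble (e.g. [psa_identity_table()] or
#'   [read_identity_table()]).
#' @param mrca_scenarios_ma Vector of assumed MRCA ages in Ma (may be
#'   empty, in which case only the identity table is reported).
#' @param anchor_divergence_pct Anchoring divergence; the conventional
#'   simplification is 30.
#' @param target_identity_pct Identity whose age is extrapolated. Default
#'   `NULL` averages the `A-vs-B` rows of `identity`.
#' @param baseline_mrca_ma MRCA age whose rate anchors the fossil
#'   consistency check (defaults to the first scenario).
#' @param out_dir Optional output directory.
#' @return An `identity_track` list: `identity`, `rates`,
#'   `extrapolations`, `consistency`, `decay_curve`, `target_identity_pct`.
#' @export
run_identity_track <- function(identity, mrca_scenarios_ma = c(2000, 2400, 3000),
                               anchor_divergence_pct = 30,
                               target_identity_pct = NULL,
                               baseline_mrca_ma = NULL,
                               out_dir = NULL) {
  identity <- tibble::as_tibble(identity)
  if (nrow(identity) == 0) abort("identity table is empty")
  if (is.null(target_identity_pct)) {
    ab <- identity$identity_pct[identity$subunit %in% "A-vs-B"]
    if (length(ab) == 0) {
      abort("no A-vs-B rows: supply target_identity_pct explicitly")
    }
    target_identity_pct <- mean(ab)
  }

  if (length(mrca_scenarios_ma) > 0) {
    scan <- mrca_sensitivity_scan(mrca_scenarios_ma, anchor_divergence_pct,
                                  target_identity_pct)
    rates <- tibble::tibble(
      mrca_age_ma = mrca_scenarios_ma,
      anchor_divergence_pct = anchor_divergence_pct,
      ma_per_pct = mrca_scenarios_ma / anchor_divergence_pct,
      ma_per_pct_reported = floor(mrca_scenarios_ma / anchor_divergence_pct)
    )
    base_mrca <- baseline_mrca_ma %||% mrca_scenarios_ma[1]
    base_rate <- calibrate_rate(base_mrca, anchor_divergence_pct)
    dated <- identity[
      !(is.na(identity$divergence_age_ma) & is.na(identity$age_min_ma) &
          is.na(identity$age_max_ma)), , drop = FALSE]
    consistency <- fossil_consistency_check(dated, base_rate)
  } else {
    scan <- rates <- consistency <- NULL
  }

  decay_curve <- identity[!is.na(identity$divergence_age_ma) |
                            !is.na(identity$age_min_ma), , drop = FALSE]
  decay_curve$age_plot_ma <- ifelse(
    is.na(decay_curve$divergence_age_ma),
    (decay_curve$age_min_ma + decay_curve$age_max_ma) / 2,
    decay_curve$divergence_age_ma
  )

  res <- structure(
    list(identity = identity, rates = rates, extrapolations = scan,
         consistency = consistency, decay_curve = decay_curve,
         target_identity_pct = target_identity_pct,
         anchor_divergence_pct = anchor_divergence_pct),
    class = "identity_track"
  )
  if (!is.null(out_dir)) write_identity_track(res, out_dir)
  res
}

#' @export
print.identity_track <- function(x, ...) {
  cat(sprintf(
    "identity_track: %d identity records; target identity %.4g%%\n",
    nrow(x$identity), x$target_identity_pct
  ))
  if (!is.null(x$extrapolations)) {
    for (i in seq_len(nrow(x$extrapolations))) {
      e <- x$extrapolations[i, ]
      cat(sprintf(
        "  MRCA %.4g Ma -> %d Ma/%% -> duplication %.2f Ga\n",
        e$mrca_age_ma, floor(e$ma_per_pct), report_age_ga(e$age_ma)
      ))
    }
  }
  invisible(x)
}

write_identity_track <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(tbl, name) {
    if (is.null(tbl)) return()
    p <- file.path(out_dir, name)
    utils::write.table(tbl, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    files[[name]] <<- p
  }
  emit(res$identity, "identity_table.tsv")
  emit(res$rates, "decay_rates.tsv")
  emit(res$extrapolations, "extrapolations.tsv")
  emit(res$consistency, "fossil_consistency.tsv")
  emit(res$decay_curve, "decay_curve.tsv")
  write_manifest(out_dir, files, extra = list(
    track = "identity",
    target_identity_pct = res$target_identity_pct,
    anchor_divergence_pct = res$anchor_divergence_pct
  ))
  invisible(out_dir)
}

#' Run the Bayesian dating track across calibration variants
#'
#' A thin orchestration over [calibration_sensitivity()]: runs the
#' relaxed-clock sampler once per calibration variant, tabulates root and
#' focus-node (duplication) posteriors per variant, and emits the paired
#' age comparisons and rate-versus-time data. Variants that fail the
#' split-R-hat threshold are flagged in the output, not fatal.
#'
#' @param alignment Alignment tibble.
#' @param tree Topology (`time_tree` or labelled `phylo`).
#' @param variants Named list of calibration tibbles.
#' @param root A [root_prior()].
#' @param focus_label Label of the duplication node to highlight.
#' @param out_dir Optional output directory for TSV reports.
#' @param ... Passed to [clock_mcmc()] (`model`, `clock`, `control`).
#' @return A `dating_track` list: `sensitivity`
#'   ([calibration_sensitivity()] object), `table`, `pairs`, `rates` (one
#'   rates-vs-time tibble per variant).
#' @export
run_dating_track <- function(alignment, tree, variants, root,
                             focus_label, out_dir = NULL, ...) {
  sens <- calibration_sensitivity(alignment, tree, variants, root,
                                  focus_label = focus_label, ...)
  rates <- purrr::imap_dfr(sens$fits, function(fit, nm) {
    dplyr::bind_cols(tibble::tibble(variant = nm), rates_vs_time(fit))
  })
  res <- structure(
    list(sensitivity = sens, table = sens$table, pairs = sens$pairs,
         rates = rates),
    class = "dating_track"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    emit <- function(tbl, name) {
      p <- file.path(out_dir, name)
      utils::write.table(tbl, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "")
      files[[name]] <<- p
    }
    emit(res$table, "variant_summary.tsv")
    emit(res$pairs, "age_pairs.tsv")
    emit(res$rates, "rates_vs_time.tsv")
    emit(sens$summaries, "node_summaries.tsv")
    write_manifest(out_dir, files, extra = list(track = "dating"))
  }
  res
}

#' @export
print.dating_track <- function(x, ...) {
  cat("dating_track across", nrow(x$table), "calibration variants\n")
  print(x$table)
  invisible(x)
}

# JSON manifest: inputs/outputs with md5 digests, package version,
# timestamp. The digests cover the deterministic payload; the timestamp is
# provenance only.
write_manifest <- function(out_dir, files, extra = list()) {
  manifest <- c(
    list(
      package = "paleoclock",
      version = as.character(utils::packageVersion("paleoclock")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      files = lapply(files, function(p) {
        list(path = basename(p), md5 = unname(tools::md5sum(p)))
      })
    ),
    extra
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
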