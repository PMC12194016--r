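#' Run the full statistical stage on a feature table
#'
#' Executes the analysis battery on an extracted [participant_features()]
#' object: quadratic time-on-task effect, strategy clustering on the
#' standardized test score and interrule time (the cluster with the higher
#' mean score is labelled *structured*), cluster contrasts (score, interrule
#' time, rule jumps), per-cluster acceleration of every time component with
#' its correlation to performance, the parallel mediation model and the
#' hierarchical ToT-vs-LFT regression within the structured cluster, the
#' response-to-difficulty summary, and the crossed mixed models of global
#' and current incomplete-attempt propensity on ToT and interrule time.
#'
#' @param features an `lft_features` object.
#' @param bootstrap mediation bootstrap resamples (default 1000).
#' @param cluster_bootstrap clustering bootstrap resamples (default 100).
#' @param k_range candidate cluster counts (default `1:10`).
#' @param seed root seed; per-stage seeds are derived substreams.
#' @return A list of class `lft_analysis` with elements `quadratic`,
#'   `clusters`, `cluster_summary`, `cluster_tests`, `acceleration`,
#'   `mediation`, `hierarchical`, `rtd`, `iap_tot`, `iap_inter`, `seed`.
#' @export
analyze_features <- function(features, bootstrap = 1000, cluster_bootstrap = 100,
                             k_range = 1:10, seed = 1L) {
  stopifnot(inherits(features, "lft_features"))
  fp <- features$participants

  quad <- quadratic_tot_effect(fp$score, fp$tot)

  cl <- ward_cluster(cbind(score = fp$score, inter = fp$inter),
                     k_range = k_range, B = cluster_bootstrap,
                     seed = substream_seed(seed, 1))
  fp$cluster <- cl$labels
  # the binary strategy contrast (structured vs unstructured) is defined on
  # the dendrogram's primary split, which coincides with the selected
  # solution when k = 2
  lab2 <- stats::cutree(cl$hclust, 2)
  means2 <- tapply(fp$score, lab2, mean)
  fp$structured <- lab2 == as.integer(names(which.max(means2)))

  cluster_summary <- fp |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(), structured = .data$structured[1],
      dplyr::across(c("score", "onset", "inter", "intra", "tot", "jump_score"),
                    list(m = mean, sd = stats::sd)),
      .groups = "drop"
    )

  cluster_tests <- NULL
  accel_tab <- NULL
  mediation <- NULL
  hierarchical <- NULL
  if (length(unique(lab2)) == 2L) {
    s <- fp[fp$structured, ]
    u <- fp[!fp$structured, ]
    cluster_tests <- dplyr::bind_rows(lapply(c("score", "inter", "jump_score"), function(v) {
      dplyr::mutate(compare_clusters(u[[v]], s[[v]]), measure = v, .before = 1)
    }))
    accel_tab <- dplyr::bind_rows(lapply(list(s, u), function(g) {
      dplyr::bind_rows(lapply(c("accel_tot", "accel_onset", "accel_inter", "accel_intra"),
                              function(v) {
        x <- g[[v]][is.finite(g[[v]])]
        tt <- stats::t.test(x)
        rr <- correlation_ci(g[[v]], g$score)
        tibble::tibble(
          cluster = if (g$structured[1]) "structured" else "unstructured",
          measure = sub("accel_", "", v),
          delta_m = mean(x), t = unname(tt$statistic), p_delta = tt$p.value,
          d = mean(x) / stats::sd(x), r_score = rr$r, p_r = rr$p
        )
      }))
    }))
    mediation <- mediation_path(s$inter, s$intra, s$jump_score, s$score,
                                B = bootstrap, seed = substream_seed(seed, 2))
    hierarchical <- hierarchical_regression(s$score, s$tot, s$onset, s$inter, s$intra)
  }

  rtd <- tibble::tibble(
    m = mean(fp$rtd_slope, na.rm = TRUE),
    sd = stats::sd(fp$rtd_slope, na.rm = TRUE),
    r2_score = correlation_ci(fp$rtd_slope, fp$score)$r^2
  )

  long <- dplyr::left_join(features$participant_items,
                           fp[c("participant_id", "iap_global")] |>
                             dplyr::rename(iap_global_p = "iap_global"),
                           by = "participant_id")
  long$iap_global <- long$iap_global_p
  iap_tot <- iap_mixed_model(long, response = "tot")
  iap_inter <- iap_mixed_model(long, response = "inter")

  structure(list(quadratic = quad, clusters = cl, participants = fp,
                 cluster_summary = cluster_summary, cluster_tests = cluster_tests,
                 acceleration = accel_tab, mediation = mediation,
                 hierarchical = hierarchical, rtd = rtd,
                 iap_tot = iap_tot, iap_inter = iap_inter, seed = seed),
            class = "lft_analysis")
}

#' One-command reproducible pipeline
#'
#' Ties the stages into a single run: simulate a cohort (or read an event
#' log and item bank), extract features, analyze, and write a report bundle.
#' All randomness derives from the single root seed via fixed per-stage
#' substreams, so a repeated run with the same configuration is
#' byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param simulate a [generator_config()] (or `TRUE` for defaults) to
#'   simulate the input cohort; mutually exclusive with `log`.
#' @param log,items paths to an event-log file and item-bank JSON.
#' @param seed root seed (default 1).
#' @param bootstrap,cluster_bootstrap,k_range passed to [analyze_features()].
#' @param inter_denominator,onset_direction passed to
#'   [participant_features()].
#' @param plots also write diagnostic plots (PDF).
#' @return The `lft_analysis` result, invisibly; the report bundle (CSV
#'   tables, `report.md`, `manifest.json`) is written to `out_dir`.
#' @export
run_pipeline <- function(out_dir,
                         simulate = NULL, log = NULL, items = NULL,
                         seed = 1L, bootstrap = 1000, cluster_bootstrap = 100,
                         k_range = 1:10,
                         inter_denominator = "transitions",
                         onset_direction = "first_on_inter",
                         plots = FALSE) {
  if (is.null(simulate) && is.null(log)) {
    abort("configuration error: need either a `simulate` block or a `log` path")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- list(seed = seed)
  if (!is.null(simulate)) {
    cfg <- if (isTRUE(simulate)) generator_config() else simulate
    cohort <- generate_cohort(cfg, seed = substream_seed(seed, 10))
    sessions <- cohort$sessions
    bank <- cohort$item_bank
    write_event_log(sessions, file.path(out_dir, "event_log.csv"))
    write_item_bank(bank, file.path(out_dir, "item_bank.json"))
    utils::write.csv(
      as.data.frame(cohort$truth$participants[
        setdiff(names(cohort$truth$participants), "rule_difficulties")]),
      file.path(out_dir, "truth_participants.csv"), row.names = FALSE)
    inputs$simulate <- TRUE
  } else {
    if (is.null(items)) abort("configuration error: `log` requires `items`")
    bank <- read_item_bank(items)
    sessions <- read_event_log(log, bank)
    inputs$log <- log
    inputs$items <- items
  }
  features <- participant_features(sessions, bank,
                                   inter_denominator = inter_denominator,
                                   onset_direction = onset_direction)
  res <- analyze_features(features, bootstrap = bootstrap,
                          cluster_bootstrap = cluster_bootstrap,
                          k_range = k_range, seed = substream_seed(seed, 20))
  render_report(res, features, out_dir, plots = plots, inputs = inputs)
  invisible(res)
}

fmt2 <- function(x) formatC(x, digits = 2, format = "f")

#' Write the report bundle
#'
#' Writes machine-readable CSV tables (item statistics, cluster summary,
#' acceleration, mediation paths, hierarchical regression, mixed-model
#' effects) plus a human-readable `report.md` with numbers formatted to two
#' decimals, and a `manifest.json` recording inputs, seeds, package version
#' and md5 checksums of every written table.
#'
#' @param results an `lft_analysis` object.
#' @param features the `lft_features` object the analysis was run on.
#' @param out_dir output directory.
#' @param plots write diagnostic PDF plots as well.
#' @param inputs named list recorded in the manifest.
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(results, features, out_dir, plots = FALSE,
                          inputs = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(as.data.frame(df), file.path(out_dir, name), row.names = FALSE)
    name
  }
  written <- character(0)
  ist <- features$item_stats
  written <- c(written, wr(ist, "item_stats.csv"))
  written <- c(written, wr(results$cluster_summary, "cluster_summary.csv"))
  written <- c(written, wr(results$quadratic, "quadratic_tot.csv"))
  if (!is.null(results$acceleration)) {
    written <- c(written, wr(results$acceleration, "acceleration.csv"))
  }
  if (!is.null(results$mediation)) {
    written <- c(written, wr(results$mediation$paths, "mediation_paths.csv"))
  }
  if (!is.null(results$hierarchical)) {
    written <- c(written, wr(results$hierarchical$coefficients, "hierarchical_regression.csv"))
  }
  iap_tab <- dplyr::bind_rows(
    dplyr::mutate(results$iap_tot$fixed, response = "tot", .before = 1),
    dplyr::mutate(results$iap_inter$fixed, response = "inter", .before = 1)
  )
  written <- c(written, wr(iap_tab, "iap_mixed_model.csv"))
  written <- c(written, wr(results$participants, "participant_features.csv"))

  md <- c(
    "# Log-file time analysis report", "",
    sprintf("Participants: %d; analysed items: %d; Cronbach alpha of the score: %s",
            nrow(results$participants), nrow(ist), fmt2(attr(ist, "alpha"))),
    "",
    "## Quadratic time-on-task effect",
    sprintf("beta_quadratic = %s, R2 = %s%%, delta R2 vs linear = %s%% (F(%d, %d) = %s, p = %.3g)",
            fmt2(results$quadratic$beta_quadratic),
            fmt2(100 * results$quadratic$r2_quadratic),
            fmt2(100 * results$quadratic$delta_r2),
            results$quadratic$df1, results$quadratic$df2,
            fmt2(results$quadratic$f_change), results$quadratic$p),
    "",
    "## Strategy clusters",
    sprintf("k = %d (average silhouette %s); sizes: %s",
            results$clusters$k, fmt2(results$clusters$silhouette),
            paste(table(results$clusters$labels), collapse = " / "))
  )
  if (!is.null(results$cluster_tests)) {
    md <- c(md, "", "Cluster contrasts (structured vs unstructured):",
            sprintf("- %s: t(%s) = %s, p = %.3g, d = %s",
                    results$cluster_tests$measure, fmt2(results$cluster_tests$df),
                    fmt2(results$cluster_tests$t), results$cluster_tests$p,
                    fmt2(results$cluster_tests$d)))
  }
  if (!is.null(results$mediation)) {
    fit <- results$mediation$fit
    md <- c(md, "", "## Mediation (structured cluster)",
            sprintf("chisq(%d) = %s, CFI = %s, RMSEA = %s, SRMR = %s",
                    fit$df, fmt2(fit$chisq), fmt2(fit$cfi), fmt2(fit$rmsea), fmt2(fit$srmr)),
            sprintf("- %s: beta = %s [%s, %s]",
                    results$mediation$paths$label,
                    fmt2(results$mediation$paths$estimate),
                    fmt2(results$mediation$paths$ci_lower),
                    fmt2(results$mediation$paths$ci_upper)))
  }
  if (!is.null(results$hierarchical)) {
    h <- results$hierarchical
    md <- c(md, "", "## Hierarchical regression (structured cluster)",
            sprintf("R2: %s%% (ToT only) -> %s%% (ToT + LFT); delta R2 = %s%% (F(%d, %d) = %s, p = %.3g)",
                    fmt2(100 * h$models$r2[1]), fmt2(100 * h$models$r2[2]),
                    fmt2(100 * h$delta_r2), h$df1, h$df2, fmt2(h$f_change), h$p_change))
  }
  md <- c(md, "", "## Incomplete-attempt propensity (mixed models)",
          sprintf("- %s ~ %s: b = %s, p = %.3g",
                  iap_tab$response, iap_tab$term, fmt2(iap_tab$estimate), iap_tab$p))
  writeLines(md, file.path(out_dir, "report.md"))
  written <- c(written, "report.md")

  if (plots) {
    fp <- results$participants
    p1 <- ggplot2::ggplot(fp, ggplot2::aes(x = .data$inter, y = .data$score,
                                           colour = factor(.data$cluster))) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "mean interrule time (s)", y = "test score",
                    colour = "cluster")
    ggplot2::ggsave(file.path(out_dir, "clusters.pdf"), p1, width = 6, height = 4)
    p2 <- ggplot2::ggplot(fp, ggplot2::aes(x = .data$tot, y = .data$score)) +
      ggplot2::geom_point() +
      ggplot2::geom_smooth(method = "lm", formula = y ~ poly(x, 2), se = FALSE) +
      ggplot2::labs(x = "mean time on task (s)", y = "test score")
    ggplot2::ggsave(file.path(out_dir, "tot_effect.pdf"), p2, width = 6, height = 4)
  }

  manifest <- list(
    package = "lftimes",
    version = as.character(utils::packageVersion("lftimes")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs,
    seed = results$seed,
    files = as.list(tools::md5sum(file.path(out_dir, setdiff(written, "report.md"))))
  )
  names(manifest$files) <- setdiff(written, "report.md")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
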