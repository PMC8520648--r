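#' Study configuration
#'
#' Bundles everything one end-to-end study run needs: the scenarios to
#' simulate (each a [sim_config()] plus a number of comparator datasets), the
#' battery configuration, and the sizes of the meta-analyses.
#'
#' @param scenarios named list; each element is a list with `config` (a
#'   [sim_config()]), `n_datasets` (>= 1) and optionally `tags` (a function of
#'   the dataset index returning a named character vector, or a fixed vector).
#' @param battery a [battery_config()].
#' @param alpha significance level for the Friedman gate and Duncan grouping.
#' @param subgroup_tag tag key for subgroup rating tables (NULL to skip).
#' @param type1_B resamples for the type-I-error table (0 to skip).
#' @param type1_methods methods assessed for type I error.
#' @param seed root seed; every dataset stream derives from it.
#' @return list of class `study_config`.
#' @export
study_config <- function(scenarios, battery = battery_config(), alpha = 0.05,
                         subgroup_tag = NULL, type1_B = 1000L,
                         type1_methods = c("MWU", "OLR"), seed = 1L) {
  stopifnot(length(scenarios) >= 1L)
  for (sc in scenarios) {
    stopifnot(inherits(sc$config, "sim_config"))
    if (is.null(sc$n_datasets) || sc$n_datasets < 1L)
      stop("every scenario needs n_datasets >= 1")
  }
  structure(list(scenarios = scenarios, battery = battery, alpha = alpha,
                 subgroup_tag = subgroup_tag, type1_B = as.integer(type1_B),
                 type1_methods = type1_methods, seed = as.integer(seed)),
            class = "study_config")
}

#' Run the full study replica
#'
#' For each scenario: simulate the comparator datasets, run the fifteen-method
#' battery on each, rank the p-values, test method differences with the
#' tie-adjusted Friedman ANOVA, group methods with Duncan's multiple range
#' test, emit overall (and optional subgroup) rating tables, estimate effects
#' and the ordinal-versus-binary sample-size multipliers, and (optionally)
#' assess type I error on a matched null dataset. All tables are written as
#' CSV under `out_dir` with a manifest recording seeds, so a run is exactly
#' reproducible. A dataset whose battery fails is logged and excluded, never
#' silently dropped.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if needed); NULL returns results
#'   without writing.
#' @return named list per scenario: `ratings`, `grouping`, `rank_matrix`,
#'   `batteries`, `samplesize`, `type1`, `subgroups`, `n_failed`.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  results <- list()
  manifest <- list(root_seed = config$seed, alpha = config$alpha,
                   scenarios = list())
  for (s in seq_along(config$scenarios)) {
    sc <- config$scenarios[[s]]
    sc_name <- names(config$scenarios)[s] %||% paste0("scenario", s)
    scale <- sc$config$scale
    batteries <- list(); tags <- character(); n_failed <- 0L
    seeds <- integer(sc$n_datasets)
    for (d in seq_len(sc$n_datasets)) {
      seeds[d] <- derive_seed(config$seed, s * 100000L + d)
      cfg <- sc$config; cfg$seed <- seeds[d]
      ds <- simulate_comparator(cfg, id = sprintf("%s_%03d", sc_name, d))
      bat <- tryCatch(run_battery(ds, scale, config = config$battery),
                      error = function(e) {
                        message("dataset ", ds$id, " failed: ",
                                conditionMessage(e)); NULL
                      })
      if (is.null(bat)) { n_failed <- n_failed + 1L; next }
      batteries[[ds$id]] <- bat
      tg <- sc$tags
      if (is.function(tg)) tg <- tg(d)
      tags <- c(tags, if (!is.null(tg) && !is.null(config$subgroup_tag))
        tg[[config$subgroup_tag]] else NA_character_)
    }
    rm <- rank_matrix(batteries)
    gr <- duncan_groups(rm, alpha = config$alpha)
    rt <- rating_table(gr)
    subgroups <- NULL
    if (!is.null(config$subgroup_tag) && !all(is.na(tags)))
      subgroups <- compare_by_subgroup(batteries, tags, alpha = config$alpha)
    # per-dataset effect estimates feed the four sample-size formulas
    ss_rows <- do.call(rbind, lapply(names(batteries), function(id) {
      cfg <- sc$config; cfg$seed <- seeds[match(id, names(batteries))]
      ds <- simulate_comparator(cfg, id = id)
      eff <- tryCatch(estimate_effects(ds, scale), error = function(e) NULL)
      if (is.null(eff) || is.na(eff$or_po) || eff$or_po == 1 ||
          eff$p_win == 0.5 || eff$delta == 0 ||
          eff$p_event[1L] == eff$p_event[2L]) return(NULL)
      data.frame(dataset = id,
                 n_binary = n_binary(eff$p_event[1L], eff$p_event[2L]),
                 n_ordinal = n_olr(eff$pbar, eff$or_po),
                 n_mwu = n_mwu(eff$p_win),
                 n_ttest = n_ttest(eff$delta, eff$sd))
    }))
    samplesize <- if (!is.null(ss_rows) && nrow(ss_rows) > 0)
      multiplier_report(ss_rows)
    type1 <- NULL
    if (config$type1_B >= 100L) {
      nullcfg <- sc$config
      nullcfg$treatment_logOR <- 0
      nullcfg$seed <- derive_seed(config$seed, s * 100000L)
      nullds <- simulate_null(nullcfg, id = paste0(sc_name, "_null"))
      type1 <- assess_type1_error(nullds, scale,
                                  methods = config$type1_methods,
                                  B = config$type1_B, alpha = config$alpha,
                                  seed = derive_seed(config$seed, s),
                                  config = config$battery)
    }
    results[[sc_name]] <- list(ratings = rt, grouping = gr, rank_matrix = rm,
                               batteries = batteries, samplesize = samplesize,
                               type1 = type1, subgroups = subgroups,
                               n_failed = n_failed)
    manifest$scenarios[[sc_name]] <- list(n_datasets = sc$n_datasets,
                                          dataset_seeds = seeds,
                                          n_failed = n_failed)
    if (!is.null(out_dir)) {
      pre <- file.path(out_dir, sc_name)
      utils::write.csv(rt, paste0(pre, "_ratings.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(rm$ranks), paste0(pre, "_ranks.csv"))
      write_battery_csv(batteries, paste0(pre, "_battery.csv"))
      if (!is.null(samplesize))
        utils::write.csv(samplesize$rows, paste0(pre, "_samplesize.csv"),
                         row.names = FALSE)
      if (!is.null(type1))
        utils::write.csv(data.frame(method = names(type1),
                                    significant = as.integer(type1),
                                    B = attr(type1, "B")),
                         paste0(pre, "_type1.csv"), row.names = FALSE)
    }
  }
  if (!is.null(out_dir))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  results
}
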