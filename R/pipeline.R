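#' Default pipeline run configuration
#'
#' A nested list documenting every tunable of the end-to-end pipeline.
#' Blocks: `cohort` (per-arm counts, asymmetry switch), `blood`
#' (`mu_mPas`, `rho_g_cm3`), `waveform` (period, pulse shape), `transient`
#' (time step, harmonic count), `stats` (t-test variant, elimination
#' tolerance, optional Benjamini-Hochberg correction — off by default to
#' mirror raw per-feature reporting — and significance level), plus the
#' outlet-lengthening applied before solving. Values can be overridden by a
#' partial list or a YAML file with the same structure.
#'
#' @param overrides partial named list (or path to a YAML file) merged over
#'   the defaults.
#' @param seed master seed recorded in the configuration.
#' @return nested configuration list.
#' @export
default_config <- function(overrides = list(), seed = 1) {
  cfg <- list(
    seed = seed,
    cohort = list(counts = as.list(.GROUP_N), asymmetry = TRUE),
    blood = list(mu_mPas = 3.5, rho_g_cm3 = 1.05),
    waveform = list(period_s = 0.137, kappa = 0.55, peak_time_frac = 0.30,
                    n_harmonics = 8),
    transient = list(time_step_s = 0.005, n_harmonics = 8),
    outlets = list(lengthen = c("out_scaL", "out_scaR"), extra_mm = 1),
    stats = list(t_variant = "student", elimination_tol = 0.05,
                 bh_correction = FALSE, alpha = 0.05, ks_mc = 500))
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  utils::modifyList(cfg, overrides)
}

.cfg_blood <- function(cfg) blood_properties(cfg$blood$mu_mPas,
                                             cfg$blood$rho_g_cm3)
.cfg_waveform <- function(cfg) default_waveform(
  cfg$waveform$period_s, cfg$waveform$kappa, cfg$waveform$peak_time_frac,
  cfg$waveform$n_harmonics)

#' Generate and write a synthetic cohort
#'
#' Samples the configured cohort and writes one network JSON per animal, a
#' `manifest.csv` (animal, group, seed, file) and a resolved-configuration
#' snapshot `config.json` sufficient to reproduce the run bit-for-bit.
#'
#' @param out_dir output directory (created if needed).
#' @param config partial configuration (see [default_config()]).
#' @param seed master seed (overrides the config's).
#' @param params group-parameter table.
#' @return invisibly, the manifest data.frame.
#' @export
run_synth <- function(out_dir, config = list(), seed = NULL,
                      params = default_group_params()) {
  cfg <- default_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ## an explicit counts override replaces the default design outright
  ## (modifyList would merge it arm-by-arm into the 7/5/10/9 defaults)
  if (is.list(config) && !is.null(config$cohort$counts))
    cfg$cohort$counts <- config$cohort$counts
  counts <- unlist(cfg$cohort$counts)
  cohort <- sample_cohort(cohort_config(counts, cfg$seed,
                                        cfg$cohort$asymmetry), params)
  manifest <- data.frame(animal = character(), group = character(),
                         seed = integer(), file = character())
  for (a in cohort) {
    file <- paste0(a$id, ".json")
    obj <- list(schema = "cowhemo-animal-1", id = a$id, group = a$group,
                inlet_velocities = as.list(a$inlet_velocities),
                network = list(schema = a$network$schema,
                               nodes = a$network$nodes,
                               segments = a$network$segments,
                               sections = a$network$sections,
                               inlets = a$network$inlets,
                               outlets = a$network$outlets,
                               angles = a$network$angles))
    jsonlite::write_json(obj, file.path(out_dir, file), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
    manifest <- rbind(manifest, data.frame(animal = a$id, group = a$group,
                                           seed = a$seed, file = file))
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read one animal file written by [run_synth()]
#' @param path animal JSON path.
#' @return a `virtual_animal`.
#' @export
read_animal_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "cowhemo-animal-1"))
    stop("not a cowhemo-animal-1 file: ", path)
  nw <- obj$network
  structure(list(id = obj$id, group = obj$group,
                 network = vascular_network(nw$nodes, nw$segments,
                                            nw$sections, nw$inlets,
                                            nw$outlets, nw$angles),
                 inlet_velocities = unlist(obj$inlet_velocities)),
            class = "virtual_animal")
}

#' Solve a cohort and tabulate its metric sets
#'
#' Runs the steady or transient solver on every animal of a generated
#' cohort (after the configured outlet lengthening) and stacks the
#' 73-feature metric sets into one tidy table. Animals whose file cannot be
#' read or whose solve fails are skipped with a warning; the run continues.
#'
#' @param cohort_dir directory written by [run_synth()], or a list of
#'   `virtual_animal` objects.
#' @param mode `"steady"` or `"transient"`.
#' @param config partial configuration.
#' @param out_file optional CSV path for the tidy table.
#' @return data.frame `animal`, `group`, `feature`, `value`, `units`,
#'   `mode`; attribute `failed` lists skipped animals.
#' @export
run_solve <- function(cohort_dir, mode = c("steady", "transient"),
                      config = list(), out_file = NULL) {
  mode <- match.arg(mode)
  cfg <- default_config(config)
  blood <- .cfg_blood(cfg)
  animals <- if (is.character(cohort_dir)) {
    manifest <- utils::read.csv(file.path(cohort_dir, "manifest.csv"),
                                stringsAsFactors = FALSE)
    lapply(manifest$file, function(f) file.path(cohort_dir, f))
  } else cohort_dir
  if (!length(animals)) stop("no animals found")
  rows <- list(); failed <- character()
  for (a in animals) {
    res <- tryCatch({
      an <- if (is.character(a)) read_animal_json(a) else a
      net <- lengthen_outlets(an$network, cfg$outlets$lengthen,
                              cfg$outlets$extra_mm)
      state <- if (mode == "steady")
        solve_steady(net, an$inlet_velocities, blood)
      else solve_transient(net, an$inlet_velocities, blood,
                           .cfg_waveform(cfg),
                           transient_config(cfg$transient$time_step_s,
                                            cfg$transient$n_harmonics))
      m <- compute_metric_set(state, net, blood)
      cbind(animal = an$id, group = an$group, m)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      nm <- if (is.character(a)) basename(a) else (a$id %||% "?")
      warning("animal ", nm, " skipped: ", conditionMessage(res),
              call. = FALSE)
      failed <- c(failed, nm)
    } else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("all animals failed to solve")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_file)) utils::write.csv(out, out_file, row.names = FALSE)
  attr(out, "failed") <- failed
  out
}

## tidy (animal, group, feature, value) -> wide animals x features
.features_wide <- function(tidy) {
  feats <- unique(tidy$feature)
  animals <- unique(tidy$animal)
  wide <- data.frame(animal = animals,
                     group = tidy$group[match(animals, tidy$animal)],
                     stringsAsFactors = FALSE)
  for (f in feats)
    wide[[f]] <- tidy$value[tidy$feature == f][
      match(animals, tidy$animal[tidy$feature == f])]
  wide
}

#' Statistical analysis of a feature table
#'
#' The full statistics stage on one feature matrix: per-feature normality
#' screen and two-group t-tests for the within-time-point comparisons
#' (1c vs 1d, 2c vs 2d), paired left/right asymmetry tests per arm (when
#' velocity columns are present), PLS-DA scores with group summaries, and
#' the two-way ANOVA (pathology, duration) on the score axes.
#'
#' @param features a wide feature data.frame (`animal`, `group`, feature
#'   columns), a tidy table from [run_solve()], or a CSV path to either.
#' @param config partial configuration.
#' @param out_dir optional directory for the result CSVs and a summary.
#' @return list with `t_tests`, `normality`, `asymmetry`, `pls`,
#'   `anova`, `significant` (feature names at the configured alpha per
#'   comparison).
#' @export
run_stats <- function(features, config = list(), out_dir = NULL) {
  cfg <- default_config(config)
  if (is.character(features))
    features <- utils::read.csv(features, stringsAsFactors = FALSE)
  if (all(c("feature", "value") %in% names(features)))
    features <- .features_wide(features)
  if (!all(c("animal", "group") %in% names(features)))
    stop("feature table must have 'animal' and 'group' columns")
  bad <- setdiff(unique(features$group), .GROUPS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  featnames <- setdiff(names(features), c("animal", "group"))
  groups <- unique(features$group)
  alpha <- cfg$stats$alpha
  ## two-group comparisons within each time point
  comps <- list(c("1c", "1d"), c("2c", "2d"))
  comps <- Filter(function(cp) all(cp %in% groups) &&
                    all(table(features$group)[cp] >= 2), comps)
  tt <- list()
  if (!length(comps))
    warning("fewer than two comparable groups: t-tests skipped")
  for (cp in comps) for (f in featnames) {
    res <- tryCatch(two_group_ttest(features, f, cp[1], cp[2],
                                    cfg$stats$t_variant),
                    error = function(e) NULL)
    if (!is.null(res)) tt[[length(tt) + 1L]] <- res
  }
  t_tests <- if (length(tt)) do.call(rbind, tt) else NULL
  if (!is.null(t_tests) && cfg$stats$bh_correction)
    t_tests$p_adjusted <- stats::p.adjust(t_tests$p_value, "BH")
  significant <- if (is.null(t_tests)) list() else {
    s <- lapply(comps, function(cp) {
      sel <- t_tests$groups == paste(cp, collapse = " vs ") &
        t_tests$p_value <= alpha
      t_tests$feature[sel]
    })
    names(s) <- vapply(comps, paste, "", collapse = "_vs_")
    s
  }
  ## normality screen
  ks <- list()
  for (g in groups) for (f in featnames) {
    x <- features[[f]][features$group == g]
    res <- tryCatch(ks_normality(x, mc = cfg$stats$ks_mc,
                                 seed = cfg$seed),
                    error = function(e) NULL)
    if (!is.null(res)) {
      res$feature <- f; res$groups <- g
      ks[[length(ks) + 1L]] <- res
    }
  }
  normality <- if (length(ks)) do.call(rbind, ks) else NULL
  ## left/right asymmetry on inlet velocities
  asym <- NULL
  if (all(c("vel_CCA_L", "vel_CCA_R") %in% featnames)) {
    rows <- lapply(groups, function(g)
      tryCatch(paired_asymmetry_test(features, "vel_CCA_L", "vel_CCA_R", g),
               error = function(e) NULL))
    asym <- do.call(rbind, Filter(Negate(is.null), rows))
  }
  ## PLS-DA + ANOVA on scores (needs >= 2 groups and complete columns)
  pls <- NULL; anova_tab <- NULL
  if (length(groups) >= 2) {
    X <- as.matrix(features[intersect(featnames, feature_registry()$feature)])
    ok <- colSums(!is.finite(X)) == 0 & apply(X, 2, stats::sd) > 0
    pls <- fit_plsda(X[, ok, drop = FALSE], features$group)
    if (all(c("1c", "1d", "2c", "2d") %in% groups)) {
      pathology <- ifelse(grepl("d$", features$group), "diabetes", "control")
      duration <- substr(features$group, 1, 1)
      anova_tab <- anova_on_scores(pls$scores, pathology, duration)
    }
  }
  out <- list(t_tests = t_tests, normality = normality, asymmetry = asym,
              pls = pls, anova = anova_tab, significant = significant,
              alpha = alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(t_tests))
      utils::write.csv(t_tests, file.path(out_dir, "t_tests.csv"),
                       row.names = FALSE)
    if (!is.null(normality))
      utils::write.csv(normality, file.path(out_dir, "normality.csv"),
                       row.names = FALSE)
    if (!is.null(asym))
      utils::write.csv(asym, file.path(out_dir, "asymmetry.csv"),
                       row.names = FALSE)
    if (!is.null(pls)) {
      utils::write.csv(data.frame(animal = features$animal,
                                  group = features$group, pls$scores),
                       file.path(out_dir, "pls_scores.csv"),
                       row.names = FALSE)
      utils::write.csv(pls$group_scores,
                       file.path(out_dir, "pls_group_scores.csv"),
                       row.names = FALSE)
    }
    if (!is.null(anova_tab))
      utils::write.csv(anova_tab, file.path(out_dir, "anova.csv"),
                       row.names = FALSE)
    writeLines(.stats_summary_text(out),
               file.path(out_dir, "summary.txt"))
  }
  out
}

.stats_summary_text <- function(res) {
  lines <- c("cowhemo statistics summary", "==========================")
  for (nm in names(res$significant))
    lines <- c(lines, sprintf("%s: %d feature(s) at p <= %.2f: %s", nm,
                              length(res$significant[[nm]]), res$alpha,
                              paste(res$significant[[nm]], collapse = ", ")))
  if (!is.null(res$asymmetry)) {
    lines <- c(lines, "", "L/R CCA-velocity asymmetry (paired t):")
    lines <- c(lines, sprintf("  group %s: t = %.2f, p = %.3g",
                              res$asymmetry$groups, res$asymmetry$statistic,
                              res$asymmetry$p_value))
  }
  if (!is.null(res$anova)) {
    lines <- c(lines, "", "Two-way ANOVA on PLS scores:")
    lines <- c(lines, sprintf("  %s, %s: F(%d,%d) = %.2f, p = %.3g",
                              res$anova$axis, res$anova$effect,
                              res$anova$df1, res$anova$df2, res$anova$F,
                              res$anova$p_value))
  }
  lines
}
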