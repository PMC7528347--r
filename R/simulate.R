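#' Configuration for the confounded expression-like simulator
#'
#' The generator emulates a toxicogenomics-style design: continuous
#' expression features grouped into feature sets (pathways), a nominal
#' compound covariate plus ordinal dose and time covariates, and a target
#' that is either continuous or a 7-level ordinal discretization. One
#' planted set (`true_set`) drives the target directly; one decoy set
#' (`decoy_set`) and the target are both driven by the covariates, creating
#' the confounding that adjustment is meant to remove. Defaults describe the
#' study conditions used throughout the package's tests: 300 samples, 10
#' sets of 12 features, 8 compounds, 4 dose and 4 time levels, signal and
#' confound effects of 2 (the confound is strong relative to the noise SD of
#' 0.5), and a 7-level ordinal target.
#'
#' @param m Samples.
#' @param n_sets,set_size Feature-set count and features per set.
#' @param true_set,decoy_set Indices of the planted signal and decoy sets.
#' @param n_compounds Levels of the nominal compound covariate.
#' @param n_dose_levels,n_time_levels Levels of the ordinal covariates.
#' @param beta_signal Effect of the true set's mean on the target.
#' @param beta_confound Effect of the covariate combination on both the
#'   decoy-set features and the target.
#' @param sigma Noise SD (> 0).
#' @param target_kind `"continuous"` or `"ordinal7"`.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m = 300, n_sets = 10, set_size = 12, true_set = 1,
                       decoy_set = 2, n_compounds = 8, n_dose_levels = 4,
                       n_time_levels = 4, beta_signal = 2, beta_confound = 2,
                       sigma = 0.5, target_kind = c("ordinal7", "continuous"),
                       seed = 1) {
  target_kind <- match.arg(target_kind)
  cfg <- list(
    m = m, n_sets = n_sets, set_size = set_size, true_set = true_set,
    decoy_set = decoy_set, n_compounds = n_compounds,
    n_dose_levels = n_dose_levels, n_time_levels = n_time_levels,
    beta_signal = beta_signal, beta_confound = beta_confound, sigma = sigma,
    target_kind = target_kind, seed = seed
  )
  if (cfg$true_set == cfg$decoy_set) abort("true_set and decoy_set must differ")
  if (cfg$sigma <= 0) abort("sigma must be > 0")
  if (!all(is.finite(c(cfg$beta_signal, cfg$beta_confound)))) abort("effect sizes must be finite")
  if (cfg$true_set > cfg$n_sets || cfg$decoy_set > cfg$n_sets) abort("planted set index out of range")
  structure(cfg, class = "sim_config")
}

#' Simulate a confounded expression-like dataset with known ground truth
#'
#' Draws covariates uniformly (compound nominal, dose and time ordinal),
#' builds a confounding signal `h` as the standardized linear combination of
#' the *encoded* covariate columns with seeded coefficients, then generates:
#' background features ~ Normal(0, 1); decoy-set features =
#' `beta_confound * h + Normal(0, sigma)`; latent target =
#' `beta_signal * mean(true-set features) + beta_confound * h +
#' Normal(0, sigma)`. An `"ordinal7"` target is the latent value discretized
#' at its empirical septiles (balanced 7 classes). The compound covariate is
#' emitted both as nominal labels and as pre-encoded base-2 bit columns; the
#' adjustment map adjusts the target and every feature by all encoded
#' covariate columns (the confounder workflow).
#'
#' @param config A [sim_config()].
#' @return A list with `table` (an [adjusted_table]), `sets` (a
#'   [feature_set_collection()]), `map` (an [adjustment_map()]) and `truth`
#'   (generative coefficients, per-sample covariates, set names).
#' @export
simulate_confounded <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  withr::with_seed(cf$seed, {
    m <- cf$m
    set_names <- sprintf("set%02d", seq_len(cf$n_sets))
    feat_names <- unlist(lapply(set_names, function(s) sprintf("%s_f%02d", s, seq_len(cf$set_size))))
    compound_levels <- sprintf("cmpd%02d", seq_len(cf$n_compounds))
    compound <- sample(compound_levels, m, replace = TRUE)
    dose <- sample.int(cf$n_dose_levels, m, replace = TRUE)
    time <- sample.int(cf$n_time_levels, m, replace = TRUE)
    bits <- binary_encode(compound, categories = compound_levels, name = "compound")
    Xc <- cbind(as.matrix(bits), dose = dose, time = time)
    w <- stats::rnorm(ncol(Xc))
    h_raw <- drop(Xc %*% w)
    h <- if (stats::sd(h_raw) > 0) drop(scale(h_raw)) else h_raw * 0

    X <- matrix(stats::rnorm(m * length(feat_names)), m,
      dimnames = list(NULL, feat_names)
    )
    decoy_cols <- sprintf("%s_f%02d", set_names[cf$decoy_set], seq_len(cf$set_size))
    X[, decoy_cols] <- cf$beta_confound * h +
      matrix(stats::rnorm(m * cf$set_size, sd = cf$sigma), m)
    true_cols <- sprintf("%s_f%02d", set_names[cf$true_set], seq_len(cf$set_size))
    latent <- cf$beta_signal * rowMeans(X[, true_cols, drop = FALSE]) +
      cf$beta_confound * h + stats::rnorm(m, sd = cf$sigma)
    if (cf$target_kind == "ordinal7") {
      cuts <- stats::quantile(latent, probs = (1:6) / 7)
      target <- as.numeric(findInterval(latent, cuts) + 1)
      tkind <- "ordinal"
    } else {
      target <- latent
      tkind <- "continuous"
    }

    data <- dplyr::bind_cols(
      tibble(sample_id = sprintf("S%03d", seq_len(m))),
      as_tibble(X),
      tibble(compound = compound),
      bits,
      tibble(dose = as.numeric(dose), time = as.numeric(time), target = target)
    )
    enc_covs <- c(names(bits), "dose", "time")
    roles <- c(
      stats::setNames(rep("feature", length(feat_names)), feat_names),
      compound = "covariate",
      stats::setNames(rep("covariate", length(enc_covs)), enc_covs),
      target = "target"
    )
    kinds <- c(
      stats::setNames(rep("continuous", length(feat_names)), feat_names),
      compound = "nominal",
      stats::setNames(rep("binary", length(names(bits))), names(bits)),
      dose = "ordinal", time = "ordinal",
      target = tkind
    )
    table <- adjusted_table(data, roles, kinds)
    sets <- feature_set_collection(
      stats::setNames(
        lapply(set_names, function(s) sprintf("%s_f%02d", s, seq_len(cf$set_size))),
        set_names
      ),
      descriptions = "simulated"
    )
    map <- adjustment_map(
      entries = stats::setNames(rep(list(enc_covs), length(feat_names)), feat_names),
      target_covariates = enc_covs
    )
    truth <- list(
      true_set = set_names[cf$true_set], decoy_set = set_names[cf$decoy_set],
      h = h, covariate_weights = w, latent = latent,
      compound = compound, dose = dose, time = time,
      beta_signal = cf$beta_signal, beta_confound = cf$beta_confound
    )
    list(table = table, sets = sets, map = map, truth = truth)
  })
}

#' Run the full preprocess-and-search chain repeatedly and tabulate
#' which feature set gets selected
#'
#' Simulates one dataset from `config`, then runs `n_runs` independent
#' searches (distinct split/GP seeds derived from `base_seed`), each with a
#' fresh 75/25 holdout and 5 shuffle CV splits, in one of two modes:
#'
#' * `"adjusted"` — target residualized by the pre-processor, features
#'   residualized in-pipeline, template
#'   `FeatureSetSelector-resAdjTransformer-Transformer-Regressor`, R² scorer;
#' * `"classic"` — no adjustment, template
#'   `FeatureSetSelector-Transformer-Regressor` (continuous target) or
#'   `...-Classifier` with balanced accuracy (ordinal target).
#'
#' The selected set of each run is the `set_name` chosen by the best
#' pipeline's Feature Set Selector. Under confounding, adjusted runs should
#' recover the planted true set while classic runs are drawn to the decoy.
#'
#' @param config A [sim_config()].
#' @param mode `"adjusted"` or `"classic"`.
#' @param gp_population,gp_generations GP sizes per run.
#' @param n_runs Number of independent runs.
#' @param base_seed Base seed; run `r` uses `base_seed + r`.
#' @param holdout_fraction Holdout proportion per run.
#' @return A tibble of class `recovery_result` with one row per run:
#'   `run`, `seed`, `selected_set`, `cv_score`, `holdout_score`; attributes
#'   `mode`, `truth`.
#' @export
recover_feature_sets <- function(config = sim_config(), mode = c("adjusted", "classic"),
                                 gp_population = 20, gp_generations = 5,
                                 n_runs = 20, base_seed = 1,
                                 holdout_fraction = 0.25) {
  mode <- match.arg(mode)
  sim <- simulate_confounded(config)
  tkind <- col_kinds(sim$table)[["target"]]
  rows <- purrr::map(seq_len(n_runs), function(r) {
    seed_r <- base_seed + r
    if (mode == "adjusted") {
      ds <- build_resadj_dataset(sim$table, sim$map,
        holdout_fraction = holdout_fraction, seed = seed_r
      )
      search <- evolve(ds,
        template = "FeatureSetSelector-resAdjTransformer-Transformer-Regressor",
        collection = sim$sets, population = gp_population,
        generations = gp_generations, seed = seed_r
      )
      hs <- search$best$holdout_score
    } else {
      m <- nrow(sim$table)
      n_hold <- round(holdout_fraction * m)
      hold_rows <- withr::with_seed(seed_r, sort(sample.int(m, n_hold)))
      keep <- setdiff(seq_len(m), hold_rows)
      tab0 <- set_table_meta(
        as_tibble(as.data.frame(sim$table))[keep, ],
        col_roles(sim$table), col_kinds(sim$table)
      )
      template <- if (tkind %in% c("binary", "ordinal")) {
        "FeatureSetSelector-Transformer-Classifier"
      } else {
        "FeatureSetSelector-Transformer-Regressor"
      }
      search <- evolve(tab0,
        template = template, collection = sim$sets,
        population = gp_population, generations = gp_generations,
        plan = make_split_plan(nrow(tab0), 5, "shuffle", 0.75, seed = seed_r),
        seed = seed_r
      )
      hold_tab <- as.data.frame(sim$table)[hold_rows, ]
      hs <- score_metric(
        search$metric, hold_tab$target, predict(search, hold_tab)
      )
    }
    fss <- purrr::detect(search$best$steps, function(s) s$role == "FeatureSetSelector")
    tibble(
      run = r, seed = seed_r,
      selected_set = fss$params$set_name,
      cv_score = search$best$cv_score, holdout_score = hs
    )
  })
  structure(dplyr::bind_rows(rows),
    mode = mode, truth = sim$truth,
    class = c("recovery_result", class(tibble()))
  )
}

#' Selection frequencies of a recovery experiment
#'
#' @param result A [recover_feature_sets()] result.
#' @return A tibble with `selected_set`, `n`, `frequency`, sorted by
#'   decreasing frequency.
#' @export
selection_frequencies <- function(result) {
  result |>
    dplyr::count(.data$selected_set, name = "n") |>
    dplyr::mutate(frequency = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n))
}
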