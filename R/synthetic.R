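#' Planted ground truth for a synthetic cohort
#'
#' Describes the generative structure of a synthetic case-control
#' immunophenotyping cohort: which variables carry a disease effect and how
#' large (standardized mean difference AD vs HC on the latent/transformed
#' scale), how the effect scales with MMSE severity band, which variables
#' carry a spousal shared-environment component and how strong
#' (within-pair correlation `rho`), per-variable age slopes and sex
#' offsets, and the base missingness rate.
#'
#' Severity multipliers are internally normalised by their expectation
#' under the cohort's MMSE band mix, so `effect_sizes` are *marginal*
#' AD-vs-HC standardized differences regardless of the gradient.
#'
#' @param n_vars number of immune variables to generate.
#' @param effect_sizes named numeric vector, variable name -> standardized
#'   AD-HC mean difference on the transformed scale.
#' @param severity_gradient named numeric vector over [mmse_bands()];
#'   relative effect multiplier per band (monotone ladder by default).
#' @param shared_env_variables character vector of variables carrying the
#'   spousal shared-environment component.
#' @param shared_env_rho within-pair correlation in `[0, 1)` for shared-env
#'   variables.
#' @param age_slopes named numeric vector, variable -> slope per SD of age.
#' @param sex_effects named numeric vector, variable -> additive offset for
#'   male subjects on the latent scale.
#' @param missingness_base_rate average fraction of cells set missing;
#'   missingness concentrates on low-baseline variables.
#' @param seed integer seed used by [generate_cohort()] by default.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_vars,
                            effect_sizes = numeric(),
                            severity_gradient = c("25-30" = 0.4, "20-24" = 0.7,
                                                  "10-19" = 1.0, "<10" = 1.3),
                            shared_env_variables = character(),
                            shared_env_rho = 0,
                            age_slopes = numeric(),
                            sex_effects = numeric(),
                            missingness_base_rate = 0.05,
                            seed = 1L) {
  if (shared_env_rho < 0 || shared_env_rho >= 1) {
    stop("shared_env_rho must be in [0, 1)")
  }
  vn <- synth_var_names(n_vars)
  planted <- union(names(effect_sizes), shared_env_variables)
  if (length(planted) > n_vars) {
    stop("n_vars smaller than the number of planted variables")
  }
  unknown <- setdiff(planted, vn)
  if (length(unknown)) {
    stop("planted variables not among generated names: ",
         paste(unknown, collapse = ", "))
  }
  if (!all(names(severity_gradient) %in% mmse_bands()) ||
      length(severity_gradient) != 4L) {
    stop("severity_gradient must be named over the four MMSE bands")
  }
  structure(
    list(n_vars = as.integer(n_vars),
         variable_names = vn,
         affected_variables = names(effect_sizes) %||% character(),
         effect_sizes = effect_sizes,
         severity_gradient = severity_gradient[mmse_bands()],
         shared_env_variables = shared_env_variables,
         shared_env_rho = shared_env_rho,
         age_slopes = age_slopes,
         sex_effects = sex_effects,
         missingness_base_rate = missingness_base_rate,
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' Canonical synthetic variable names
#'
#' Hierarchical-style population labels (`lineage/subset/popNNN`) cycling
#' over common leukocyte lineages, so synthetic tables look like real
#' gating exports.
#'
#' @param n_vars number of names.
#' @return Character vector of length `n_vars`.
#' @export
synth_var_names <- function(n_vars) {
  lineages <- c("B/naive", "B/memory", "T/CD4", "T/CD8", "NK", "mono", "DC")
  sprintf("%s/pop%04d", lineages[(seq_len(n_vars) - 1L) %% length(lineages) + 1L],
          seq_len(n_vars))
}

# MMSE band mix used for AD subjects (empirical memory-clinic mix).
.mmse_mix <- c("25-30" = 33, "20-24" = 48, "10-19" = 80, "<10" = 23) / 184

#' Generate a synthetic case-control cohort with planted structure
#'
#' Frequencies are generated as `exp`-transformed Gaussian latents scaled
#' to percent-of-parent units: for subject i and variable v,
#' `latent = age_slope_v * z(age_i) + sex_effect_v * 1(male) +
#' effect_v * severity_mult_i * 1(AD) + shared-pair component + noise`,
#' and `freq = min(100, baseline_v * exp(scale_v * latent))`. Effects are
#' planted on the latent scale so that Box-Cox transformation plus
#' z-scoring approximately recovers them. Shared-environment variables
#' split the unit noise variance into a pair-shared part (`rho`) and an
#' individual part (`1 - rho`). Missingness is applied cell-wise with a
#' per-variable probability that decreases in baseline frequency
#' (missing-at-random given the baseline, mean rate =
#' `missingness_base_rate`).
#'
#' A subset of HC subjects are assigned as spouses of AD subjects
#' (opposite sex, closely matched age); AD and HC ages are drawn from the
#' same truncated-normal law.
#'
#' @param n_ad,n_hc numbers of AD and HC subjects.
#' @param truth a [synthetic_truth()].
#' @param n_pairs number of spousal pairs; default `min(n_ad, n_hc)`.
#' @param age_range inclusive age range in years; default 45-83.
#' @param seed integer seed; defaults to `truth$seed`.
#' @return A list with `table` (a [cohort_table()]), `meta` (metadata
#'   data.frame) and `truth` (the input truth augmented with realised
#'   `baselines`, `log_scale` and `miss_prob` per variable).
#' @export
generate_cohort <- function(n_ad, n_hc, truth,
                            n_pairs = min(n_ad, n_hc),
                            age_range = c(45, 83),
                            seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_pairs > min(n_ad, n_hc)) stop("n_pairs exceeds min(n_ad, n_hc)")
  nv <- truth$n_vars
  vn <- truth$variable_names
  rho <- truth$shared_env_rho

  with_seed(seed, {
    ids_ad <- sprintf("AD%04d", seq_len(n_ad))
    ids_hc <- sprintf("HC%04d", seq_len(n_hc))
    ids <- c(ids_ad, ids_hc)
    n <- n_ad + n_hc

    rtruncnorm <- function(n, mean, sd) {
      x <- rnorm(n, mean, sd)
      while (any(bad <- x < age_range[1] | x > age_range[2])) {
        x[bad] <- rnorm(sum(bad), mean, sd)
      }
      x
    }
    age_ad <- round(rtruncnorm(n_ad, 70, 9))
    sex_ad <- sample(c("M", "F"), n_ad, replace = TRUE)

    paired_ad <- sort(sample.int(n_ad, n_pairs))
    age_hc <- round(rtruncnorm(n_hc, 70, 9))
    sex_hc <- sample(c("M", "F"), n_hc, replace = TRUE)
    # spouses: opposite sex, age matched to partner
    age_hc[seq_len(n_pairs)] <-
      round(pmin(age_range[2], pmax(age_range[1],
                                    age_ad[paired_ad] + rnorm(n_pairs, 0, 3))))
    sex_hc[seq_len(n_pairs)] <- ifelse(sex_ad[paired_ad] == "M", "F", "M")

    spouse <- rep(NA_character_, n)
    spouse[paired_ad] <- ids_hc[seq_len(n_pairs)]
    spouse[n_ad + seq_len(n_pairs)] <- ids_ad[paired_ad]

    band <- sample(mmse_bands(), n_ad, replace = TRUE, prob = .mmse_mix)
    sev <- truth$severity_gradient / sum(truth$severity_gradient * .mmse_mix)
    mult <- c(sev[band], rep(0, n_hc))

    age <- c(age_ad, age_hc)
    sex <- c(sex_ad, sex_hc)
    group <- rep(c("AD", "HC"), c(n_ad, n_hc))
    zage <- (age - mean(age)) / sd(age)

    baselines <- 10^runif(nv, -2, 1.5)          # percent of parent
    log_scale <- runif(nv, 0.3, 0.6)

    fill <- function(v) {
      out <- setNames(numeric(nv), vn)
      if (length(v)) out[names(v)] <- v
      out
    }
    eff <- fill(truth$effect_sizes)
    slp <- fill(truth$age_slopes)
    sxe <- fill(truth$sex_effects)
    shared <- vn %in% truth$shared_env_variables

    pair_of <- rep(NA_integer_, n)
    pair_of[paired_ad] <- seq_len(n_pairs)
    pair_of[n_ad + seq_len(n_pairs)] <- seq_len(n_pairs)

    eps <- matrix(rnorm(n * nv), n, nv)
    if (any(shared) && rho > 0 && n_pairs > 0) {
      s_pair <- matrix(rnorm(n_pairs * sum(shared)), n_pairs, sum(shared))
      paired <- !is.na(pair_of)
      eps[paired, shared] <- sqrt(rho) * s_pair[pair_of[paired], , drop = FALSE] +
        sqrt(1 - rho) * eps[paired, shared, drop = FALSE]
    }

    latent <- eps +
      outer(zage, slp) +
      outer(as.numeric(sex == "M"), sxe) +
      outer(mult * (group == "AD"), rep(1, nv)) * matrix(eff, n, nv, byrow = TRUE)

    freq <- pmin(matrix(baselines, n, nv, byrow = TRUE) *
                   exp(matrix(log_scale, n, nv, byrow = TRUE) * latent), 100)
    dimnames(freq) <- list(ids, vn)

    # missingness preferentially in low-baseline variables; mean = base rate
    r <- rank(baselines, ties.method = "average")
    miss_prob <- truth$missingness_base_rate * 2 * (nv - r + 0.5) / nv
    if (truth$missingness_base_rate > 0) {
      mask <- matrix(runif(n * nv), n, nv) <
        matrix(miss_prob, n, nv, byrow = TRUE)
      freq[mask] <- NA_real_
    }

    meta <- data.frame(
      subject_id = ids, group = group, age = age, sex = sex,
      spouse_id = spouse,
      mmse_band = c(band, rep(NA_character_, n_hc)),
      apoe_e4 = c(runif(n_ad) < 102 / 184, runif(n_hc) < 22 / 105),
      ebv_pos = runif(n) < 0.90,
      cmv_pos = runif(n) < 0.55,
      Abeta42_ttau = c(exp(rnorm(n_ad, -0.5, 0.4)), rep(NA_real_, n_hc)),
      Abeta42_ptau181 = c(exp(rnorm(n_ad, 1.2, 0.4)), rep(NA_real_, n_hc)),
      ptau217 = c(exp(rnorm(n_ad, -1, 0.5)), rep(NA_real_, n_hc)),
      stringsAsFactors = FALSE
    )
    meta <- validate_subjects(meta)

    truth$baselines <- setNames(baselines, vn)
    truth$log_scale <- setNames(log_scale, vn)
    truth$miss_prob <- setNames(miss_prob, vn)
    truth$seed <- as.integer(seed)

    list(table = cohort_table(freq, provenance = sprintf("synthetic cohort seed %d", seed)),
         meta = meta, truth = truth)
  })
}

#' Export planted ground truth to JSON
#'
#' @param truth a `synthetic_truth` (optionally augmented by
#'   [generate_cohort()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  x <- unclass(truth)
  # named numeric vectors must become JSON objects, not bare arrays
  for (nm in c("effect_sizes", "severity_gradient", "age_slopes",
               "sex_effects", "baselines", "log_scale", "miss_prob")) {
    if (!is.null(x[[nm]])) x[[nm]] <- as.list(x[[nm]])
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read planted ground truth back from JSON
#'
#' Inverse of [export_truth()]; named maps come back as named numeric
#' vectors, so a write/read round trip is the identity.
#'
#' @param path JSON path written by [export_truth()].
#' @return A `synthetic_truth`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("effect_sizes", "severity_gradient", "age_slopes",
               "sex_effects", "baselines", "log_scale", "miss_prob")) {
    if (!is.null(x[[nm]])) x[[nm]] <- unlist(x[[nm]])
    if (!is.null(x[[nm]]) && !length(x[[nm]])) x[[nm]] <- numeric()
  }
  for (nm in c("variable_names", "affected_variables", "shared_env_variables")) {
    if (is.null(x[[nm]])) x[[nm]] <- character() else x[[nm]] <- as.character(unlist(x[[nm]]))
  }
  x$n_vars <- as.integer(x$n_vars)
  x$seed <- as.integer(x$seed)
  structure(x, class = "synthetic_truth")
}
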