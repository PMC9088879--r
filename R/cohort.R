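#' Default covariate distribution parameters for synthetic cohorts
#'
#' Per-variable generating parameters for the synthetic patient cohort,
#' calibrated to published group summaries of patients imaged by coronary
#' CT after stent implantation: binary risk factors as group proportions,
#' continuous demographics/laboratory values as group means and SDs (units
#' in the names where conventional: mmol/L for cholesterol fractions, g/L
#' for apolipoproteins, mg/L for hs-CRP, U/L for CPK). Covariates are
#' generated independently of one another.
#'
#' @return Named list; each element is
#'   `list(type = "binary", p = c(nonisr, isr))` or
#'   `list(type = "normal", mean = c(nonisr, isr), sd = c(nonisr, isr))`.
#' @export
default_covariates <- function() {
  bin <- function(p0, p1) list(type = "binary", p = c(p0, p1))
  nrm <- function(m0, s0, m1, s1)
    list(type = "normal", mean = c(m0, m1), sd = c(s0, s1))
  list(
    age = nrm(66.2, 9.9, 68.0, 11.0),
    male = bin(44 / 65, 39 / 52),
    hyperlipidemia = bin(17 / 65, 15 / 52),
    diabetes = bin(22 / 65, 18 / 52),
    hypertension = bin(31 / 65, 28 / 52),
    smoking = bin(23 / 65, 21 / 52),
    prior_mi = bin(8 / 65, 12 / 52),
    hemoglobin = nrm(135.3, 14.1, 131.0, 22.2),
    total_bilirubin = nrm(10.8, 4.5, 11.2, 4.9),
    direct_bilirubin = nrm(3.0, 1.4, 3.4, 1.8),
    indirect_bilirubin = nrm(7.8, 3.7, 7.7, 3.4),
    creatinine = nrm(75.4, 14.2, 83.6, 32.0),
    cpk = nrm(93.6, 38.3, 117.0, 72.3),
    bnp = nrm(65.2, 46.1, 199.5, 495.1),
    total_cholesterol = nrm(3.5, 0.9, 3.5, 0.9),
    hdl_c = nrm(1.3, 0.3, 1.2, 0.2),
    ldl_c = nrm(2.0, 0.7, 2.0, 0.8),
    tg = nrm(1.6, 1.0, 1.4, 0.8),
    apoa1 = nrm(1.2, 0.2, 1.1, 0.2),
    apob = nrm(0.7, 0.2, 0.7, 0.3),
    apoe = nrm(3.6, 1.4, 3.3, 1.1),
    platelet = nrm(183.7, 43.5, 188.5, 63.3),
    erythrocytes = nrm(4.4, 0.4, 4.3, 0.6),
    leucocytes = nrm(6.0, 1.6, 6.4, 2.0),
    rdw = nrm(12.9, 0.9, 13.4, 1.8),
    lymphocytes = nrm(1.7, 0.7, 1.7, 0.7),
    neutrophils = nrm(3.5, 1.2, 3.9, 1.6),
    monocytes = nrm(0.5, 0.2, 0.5, 0.2),
    hs_crp = nrm(2.8, 3.6, 4.6, 6.6),
    hba1c = nrm(6.4, 1.2, 6.6, 1.1),
    months_since_pci = nrm(37.09, 14.70, 33.85, 14.12),
    stent_length = nrm(28.0, 12.1, 28.0, 9.8),
    stent_diameter = nrm(4.2, 0.5, 4.2, 0.5),
    des = bin(58 / 65, 43 / 52)
  )
}

#' Configuration for a synthetic patient cohort
#'
#' Generating parameters for a two-group (ISR vs non-ISR) cohort: group
#' sizes, peri-stent FAI normal parameters per group, covariate
#' distributions, vessel and segment location proportions, the ISR-degree
#' distribution (truncated to \[0, 100\] %), and the target Pearson
#' correlation between degree and FAI within the ISR group (induced by a
#' Gaussian copula: bivariate normal, degree then clipped).
#'
#' @param n_isr,n_nonisr Group sizes (>= 0).
#' @param fai_isr,fai_nonisr `c(mean, sd)` of peri-stent FAI, HU.
#' @param degree `c(mean, sd)` of the degree of ISR, percent (ISR group).
#' @param degree_fai_cor Target Pearson correlation between degree and FAI
#'   in the ISR group (|r| < 1).
#' @param vessel_props Named list with per-group probabilities over
#'   `c(LAD, LCx, RCA)`.
#' @param segment_props Named list with per-group probabilities over
#'   `c(proximal, middle, distal)`.
#' @param vessel_fai Optional named list (`LAD`, `LCx`, `RCA`) of lists with
#'   `isr`/`nonisr` `c(mean, sd)` overriding the global FAI parameters per
#'   vessel.
#' @param covariates Covariate parameter list ([default_covariates()]).
#' @param seed RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_isr = 52, n_nonisr = 65,
                          fai_isr = c(mean = -78.1, sd = 6.2),
                          fai_nonisr = c(mean = -87.2, sd = 7.3),
                          degree = c(mean = 50.3, sd = 21.5),
                          degree_fai_cor = 0.579,
                          vessel_props = list(
                            nonisr = c(LAD = 40, LCx = 9, RCA = 16) / 65,
                            isr = c(LAD = 33, LCx = 11, RCA = 8) / 52),
                          segment_props = list(
                            nonisr = c(proximal = 26, middle = 36, distal = 3) / 65,
                            isr = c(proximal = 25, middle = 24, distal = 3) / 52),
                          vessel_fai = NULL,
                          covariates = default_covariates(),
                          seed = 1) {
  if (!is_number(n_isr) || !is_number(n_nonisr) || n_isr < 0 || n_nonisr < 0)
    stopf("group sizes must be >= 0")
  if (abs(degree_fai_cor) >= 1)
    stopf("|degree_fai_cor| must be < 1")
  if (degree[2] < 0 || fai_isr[2] < 0 || fai_nonisr[2] < 0)
    stopf("SDs must be >= 0")
  for (p in c(vessel_props, segment_props))
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-6)
      stopf("location proportions must lie in [0,1] and sum to 1")
  structure(list(n_isr = as.integer(n_isr), n_nonisr = as.integer(n_nonisr),
                 fai_isr = fai_isr, fai_nonisr = fai_nonisr,
                 degree = degree, degree_fai_cor = degree_fai_cor,
                 vessel_props = vessel_props, segment_props = segment_props,
                 vessel_fai = vessel_fai, covariates = covariates,
                 seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic patient cohort
#'
#' Draws a two-group cohort from the configured distributions: per-group
#' FAI Normal; binary covariates Bernoulli; continuous covariates Normal;
#' vessel/segment locations multinomial. Within the ISR group, (degree,
#' FAI) pairs are bivariate normal at the configured correlation, with the
#' degree clipped to \[0, 100\] %. Deterministic under a fixed seed.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` with columns `id`, `isr` (0/1),
#'   `peri_stent_fai_hu`, `degree_of_isr` (`NA` for non-ISR), `vessel`,
#'   `segment`, `stent_class`, plus one column per configured covariate.
#' @export
generate_cohort <- function(config = cohort_config()) {
  cfg <- config
  n1 <- cfg$n_isr; n0 <- cfg$n_nonisr
  n <- n0 + n1
  grp <- rep(c(0L, 1L), c(n0, n1))
  with_seed(cfg$seed, {
    vessel <- c(
      sample(names(cfg$vessel_props$nonisr), n0, TRUE,
             prob = cfg$vessel_props$nonisr),
      sample(names(cfg$vessel_props$isr), n1, TRUE,
             prob = cfg$vessel_props$isr))
    segment <- c(
      sample(names(cfg$segment_props$nonisr), n0, TRUE,
             prob = cfg$segment_props$nonisr),
      sample(names(cfg$segment_props$isr), n1, TRUE,
             prob = cfg$segment_props$isr))

    fai_par <- function(v, isr) {
      if (!is.null(cfg$vessel_fai) && v %in% names(cfg$vessel_fai)) {
        p <- cfg$vessel_fai[[v]][[if (isr) "isr" else "nonisr"]]
      } else p <- if (isr) cfg$fai_isr else cfg$fai_nonisr
      unname(p)
    }
    # standard-normal scores; FAI scaled per subject (vessel overrides)
    z_fai <- stats::rnorm(n)
    par_mat <- t(vapply(seq_len(n),
                        function(i) fai_par(vessel[i], grp[i] == 1L),
                        numeric(2)))
    fai <- par_mat[, 1] + par_mat[, 2] * z_fai
    degree <- rep(NA_real_, n)
    if (n1 > 0) {
      rho <- cfg$degree_fai_cor
      z_deg <- rho * z_fai[grp == 1L] +
        sqrt(1 - rho^2) * stats::rnorm(n1)
      degree[grp == 1L] <- pmin(pmax(cfg$degree[1] + cfg$degree[2] * z_deg,
                                     0), 100)
    }
    stent_class <- rep("DES", n)
    cov_cols <- list()
    for (nm in names(cfg$covariates)) {
      p <- cfg$covariates[[nm]]
      if (p$type == "binary") {
        col <- stats::rbinom(n, 1L, p$p[grp + 1L])
      } else {
        col <- stats::rnorm(n, p$mean[grp + 1L], p$sd[grp + 1L])
      }
      cov_cols[[nm]] <- col
    }
    if ("des" %in% names(cov_cols))
      stent_class <- ifelse(cov_cols$des == 1L, "DES", "BMS")
  })
  out <- data.frame(id = seq_len(n), isr = grp,
                    peri_stent_fai_hu = fai, degree_of_isr = degree,
                    vessel = vessel, segment = segment,
                    stent_class = stent_class,
                    stringsAsFactors = FALSE)
  if (length(cov_cols)) out <- cbind(out, as.data.frame(cov_cols))
  out
}
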