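#' Two-genotype mean-field tissue model
#'
#' Deterministic compartment model of interfollicular epidermis carrying a
#' wild-type and a mutant genotype.  Per genotype the model tracks basal
#' progenitor density P, differentiated basal density D and suprabasal
#' density S (cells per unit basal area), with dynamics
#' \deqn{dP/dt = \lambda \Delta_{eff} P}
#' \deqn{dD/dt = \lambda (1 - \Delta_{eff}) P - \Gamma D}
#' \deqn{dS/dt = \Gamma D - \mu S}
#' An optional crowding feedback attenuates the fate imbalance as total
#' basal density rises: \eqn{\Delta_{eff} = \Delta \max(0, 1 - k (B/B_0 - 1))}.
#'
#' The wild type must be homeostatic (`delta = 0`); its compartments are
#' initialised at the steady state `D = lam P / gamma`, `S = lam P / mu`.
#' The mutant starts as a fraction `init_mutant_fraction` of basal cells
#' with the same basal composition; its suprabasal compartment starts empty
#' (labelled cells reach the suprabasal layer only by stratification),
#' unless `init_mutant_suprabasal = TRUE`.
#'
#' @param wt,mut [sp_params()] objects for the two genotypes.
#' @param init_mutant_fraction initial mutant fraction of basal cells.
#' @param feedback_strength crowding feedback coefficient `k >= 0`
#'   (0 disables).
#' @param basal_density total initial basal density `B_0` (arbitrary
#'   units; defaults to 1).
#' @param init_mutant_suprabasal start the mutant suprabasal compartment at
#'   its proportional share rather than empty.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(wt = sp_params(), mut = sp_params(),
                          init_mutant_fraction = 0.01,
                          feedback_strength = 0,
                          basal_density = 1,
                          init_mutant_suprabasal = FALSE) {
  stopifnot(inherits(wt, "sp_params"), inherits(mut, "sp_params"),
            init_mutant_fraction >= 0, init_mutant_fraction <= 1,
            feedback_strength >= 0, basal_density > 0)
  if (abs(wt$delta) > 1e-12)
    stop("wild type must be homeostatic (delta = 0)")
  if (wt$gamma <= 0 || wt$mu <= 0)
    stop("wild-type gamma and mu must be positive for a homeostatic steady state")
  structure(list(wt = wt, mut = mut,
                 init_mutant_fraction = init_mutant_fraction,
                 feedback_strength = feedback_strength,
                 basal_density = basal_density,
                 init_mutant_suprabasal = init_mutant_suprabasal),
            class = "tissue_params")
}

.tissue_init <- function(tp) {
  f <- tp$init_mutant_fraction
  wt <- tp$wt
  # basal composition shares at the wild-type steady state
  p_share <- 1 / (1 + wt$lam / wt$gamma)
  B0 <- tp$basal_density
  S0 <- wt$lam * (B0 * p_share) / wt$mu
  c(P_wt = (1 - f) * B0 * p_share,
    D_wt = (1 - f) * B0 * (1 - p_share),
    S_wt = if (tp$init_mutant_suprabasal) (1 - f) * S0 else S0,
    P_mut = f * B0 * p_share,
    D_mut = f * B0 * (1 - p_share),
    S_mut = if (tp$init_mutant_suprabasal) f * S0 else 0)
}

#' Integrate the mean-field tissue model
#'
#' @param tp a [tissue_params()] object.
#' @param t_grid increasing time grid in weeks, starting at 0.
#' @param init optional state vector (named as the return columns) to
#'   continue a previous trajectory, e.g. for piecewise parameter changes.
#' @return An object of class `tissue_trajectory`: data frame with time,
#'   the six compartment densities, labelled (mutant) basal and suprabasal
#'   fractions and the thickness proxy `1 + S_total / B_total`.
#' @examples
#' tp <- tissue_params(mut = sp_params(delta = 0.2, mu = 0.2))
#' traj <- simulate_mean_field(tp, seq(0, 12, by = 0.25))
#' tail(traj[, c("time_weeks", "basal_frac", "supra_frac", "thickness")], 2)
#' @export
simulate_mean_field <- function(tp, t_grid = seq(0, 12, by = 0.1),
                                init = NULL) {
  stopifnot(inherits(tp, "tissue_params"),
            !is.unsorted(t_grid, strictly = TRUE))
  y0 <- if (is.null(init)) .tissue_init(tp) else init
  B0 <- tp$basal_density
  k <- tp$feedback_strength
  rhs <- function(t, y, parms) {
    B <- y[1] + y[2] + y[4] + y[5]
    atten <- if (k > 0) max(0, 1 - k * (B / B0 - 1)) else 1
    g <- function(p, P, D, S, d_eff) {
      c(p$lam * d_eff * P,
        p$lam * (1 - d_eff) * P - p$gamma * D,
        p$gamma * D - p$mu * S)
    }
    list(c(g(tp$wt, y[1], y[2], y[3], tp$wt$delta * atten),
           g(tp$mut, y[4], y[5], y[6], tp$mut$delta * atten)))
  }
  sol <- deSolve::ode(y = y0, times = t_grid, func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  out <- as.data.frame(sol)
  names(out) <- c("time_weeks", "P_wt", "D_wt", "S_wt",
                  "P_mut", "D_mut", "S_mut")
  B_tot <- out$P_wt + out$D_wt + out$P_mut + out$D_mut
  S_tot <- out$S_wt + out$S_mut
  out$basal_frac <- (out$P_mut + out$D_mut) / B_tot
  out$supra_frac <- ifelse(S_tot > 0, out$S_mut / S_tot, 0)
  out$thickness <- 1 + S_tot / B_tot
  structure(out, class = c("tissue_trajectory", "data.frame"))
}

#' Thickness proxy of a trajectory
#'
#' Dimensionless layer-count proxy `1 + S_total / B_total`; constant for a
#' homeostatic tissue.  (Mapping to micrometres is out of scope.)
#'
#' @param traj a [simulate_mean_field()] trajectory.
#' @return Numeric series, one value per time point.
#' @export
thickness_proxy <- function(traj) {
  stopifnot(inherits(traj, "tissue_trajectory"))
  traj$thickness
}

#' Tidy long-format export of a trajectory
#'
#' @param traj a [simulate_mean_field()] trajectory.
#' @return Data frame `time_weeks, genotype, compartment, density`.
#' @export
tidy_trajectory <- function(traj) {
  stopifnot(inherits(traj, "tissue_trajectory"))
  comp <- expand.grid(compartment = c("P", "D", "S"),
                      genotype = c("wt", "mut"), stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(comp)), function(i) {
    col <- paste0(comp$compartment[i], "_", comp$genotype[i])
    data.frame(time_weeks = traj$time_weeks, genotype = comp$genotype[i],
               compartment = comp$compartment[i], density = traj[[col]])
  }))
}

#' Named mechanistic hypotheses for mutant suprabasal accumulation
#'
#' Returns the default perturbations applied to the mutant genotype:
#' a change in the proportion of symmetric divisions (`r`), a
#' stratification-rate decrease, a shedding-rate decrease, a cell-fate
#' imbalance, and fate imbalance combined with reduced shedding.
#'
#' @param delta fate imbalance magnitude used by the imbalance hypotheses.
#' @param shed_factor fold-reduction of the mutant shedding rate.
#' @param strat_factor fold-reduction of the mutant stratification rate.
#' @param r_new symmetric-division proportion for the `symmetric_change`
#'   hypothesis.
#' @return Named list of functions, each mapping wild-type [sp_params()]
#'   to the perturbed mutant parameters.
#' @export
default_hypotheses <- function(delta = 0.2, shed_factor = 5,
                               strat_factor = 5, r_new = 0.45) {
  list(
    symmetric_change = function(wt)
      sp_params(r = r_new, lam = wt$lam, delta = 0, gamma = wt$gamma, mu = wt$mu),
    stratification_decrease = function(wt)
      sp_params(r = wt$r, lam = wt$lam, delta = 0,
                gamma = wt$gamma / strat_factor, mu = wt$mu),
    shedding_decrease = function(wt)
      sp_params(r = wt$r, lam = wt$lam, delta = 0, gamma = wt$gamma,
                mu = wt$mu / shed_factor),
    fate_imbalance = function(wt)
      sp_params(r = wt$r, lam = wt$lam, delta = delta, gamma = wt$gamma,
                mu = wt$mu),
    imbalance_plus_shedding = function(wt)
      sp_params(r = wt$r, lam = wt$lam, delta = delta, gamma = wt$gamma,
                mu = wt$mu / shed_factor)
  )
}

#' Scan mechanistic hypotheses against qualitative tissue signatures
#'
#' Each hypothesis perturbs the mutant genotype, the tissue model is
#' integrated, and three signatures of the observed mutant phenotype are
#' evaluated as explicit inequalities on the trajectory:
#' \describe{
#'   \item{S1 basal rise}{the labelled basal fraction rises progressively:
#'     above its initial value and still growing over the second half of
#'     the course (`frac(T) > (1 + tol) * frac(T/2)`).}
#'   \item{S2 suprabasal faster}{the labelled suprabasal fraction exceeds
#'     the labelled basal fraction at the final time by factor `1 + tol`.}
#'   \item{S3 thickening}{the thickness proxy at the final time exceeds
#'     its initial value by factor `1 + tol_thick`.}
#' }
#'
#' @param base a [tissue_params()] object giving the wild type and initial
#'   conditions; its mutant slot is replaced per hypothesis.
#' @param hypotheses named list as from [default_hypotheses()], or a
#'   character vector of names drawn from it.
#' @param t_max end of the simulated course (weeks).
#' @param tol relative tolerance of the fraction inequalities.
#' @param tol_thick relative tolerance of the thickness inequality.
#' @return Data frame: one row per hypothesis with logical columns
#'   `basal_rise`, `supra_faster`, `thickening` and `all_signatures`.
#' @export
hypothesis_scan <- function(base = tissue_params(),
                            hypotheses = default_hypotheses(),
                            t_max = 12, tol = 0.05, tol_thick = 0.02) {
  stopifnot(inherits(base, "tissue_params"))
  if (is.character(hypotheses)) {
    all_h <- default_hypotheses()
    bad <- setdiff(hypotheses, names(all_h))
    if (length(bad))
      stop("unknown hypothesis: ", paste(bad, collapse = ", "),
           "; valid names: ", paste(names(all_h), collapse = ", "))
    hypotheses <- all_h[hypotheses]
  }
  t_grid <- seq(0, t_max, length.out = 241)
  i_mid <- which.min(abs(t_grid - t_max / 2))
  n <- length(t_grid)
  rows <- lapply(names(hypotheses), function(h) {
    tp <- base
    tp$mut <- hypotheses[[h]](base$wt)
    tr <- simulate_mean_field(tp, t_grid)
    s1 <- tr$basal_frac[n] > tr$basal_frac[1] &&
      tr$basal_frac[n] > (1 + tol) * tr$basal_frac[i_mid]
    s2 <- tr$supra_frac[n] > (1 + tol) * tr$basal_frac[n]
    s3 <- tr$thickness[n] > (1 + tol_thick) * tr$thickness[1]
    data.frame(hypothesis = h, basal_rise = s1, supra_faster = s2,
               thickening = s3, all_signatures = s1 && s2 && s3)
  })
  do.call(rbind, rows)
}
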