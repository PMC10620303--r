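# Random search for admissible multigenerational parameter sets.
# The published figures rely on a parameter table not reproduced here, so
# working parameter sets are found by seeded log-uniform sampling and kept
# with full provenance (seed, try index).

#' Default sampling bounds for the admissible-set search
#'
#' Log-uniform ranges per parameter class, chosen so that a substantial
#' fraction of sampled haploid activator-inhibitor systems sit in the
#' self-activating, Turing-capable regime: baseline production `alpha` well
#' below the regulated production `gamma`, degradation `beta` of order one
#' (setting the time unit), and binding constants `kappa` such that the Hill
#' terms operate near half-saturation.
#'
#' @return Named list of `c(lo, hi)` ranges for `alpha`, `beta`, `gamma`,
#'   `kappa`, and `m` (trans/cis efficacy ratios, symmetric mode only).
#' @export
default_search_bounds <- function() {
  list(alpha = c(1e-3, 5e-2), beta = c(0.5, 2), gamma = c(5, 50),
       kappa = c(1, 50), m = c(0.1, 0.9))
}

draw_params_general <- function(bounds) {
  rates <- lapply(setNames(nm = rate_keys()), function(k)
    c(alpha = runif_log(1, bounds$alpha[1], bounds$alpha[2]),
      beta = runif_log(1, bounds$beta[1], bounds$beta[2]),
      gamma = runif_log(1, bounds$gamma[1], bounds$gamma[2])))
  kappa <- setNames(runif_log(16, bounds$kappa[1], bounds$kappa[2]),
                    kappa_keys())
  list(rates = rates, kappa = kappa)
}

# symmetric-parents draw: allele-independent parent kinetics and cis binding
# constants, plus one reduced trans efficacy m_vu (activator regulating
# inhibitor) -- the mechanism by which identical unpatterned parents yield a
# patterned F1. Parents whose single-axis efficacy responses are not in the
# modal regime (reducing m_uv or m_vu lowers d*, reducing m_uu or m_vv
# raises it) are rejected so the packaged limit case is representative.
draw_params_symmetric <- function(bounds) {
  base <- lapply(setNames(nm = TFS), function(t)
    c(alpha = runif_log(1, bounds$alpha[1], bounds$alpha[2]),
      beta = runif_log(1, bounds$beta[1], bounds$beta[2]),
      gamma = runif_log(1, bounds$gamma[1], bounds$gamma[2])))
  parent_rates <- list(u = base$u, v = base$v)
  parent_kappa <- setNames(runif_log(4, bounds$kappa[1], bounds$kappa[2]),
                           c("uu", "uv", "vu", "vv"))
  m_vu <- runif_log(1, bounds$m[1], bounds$m[2])
  m <- trans_efficacy(m_vu = m_vu)
  rates <- lapply(setNames(nm = rate_keys()), function(k)
    base[[substr(k, 1, 1)]])
  kappa <- setNames(numeric(16), kappa_keys())
  for (key in kappa_keys()) {
    pair <- substr(key, 1, 2)
    cis_pair <- substr(key, 4, 5) %in% c("AA", "BB")
    kappa[key] <- parent_kappa[pair] * if (cis_pair) 1 else
      as.numeric(m[pair])
  }
  list(rates = rates, kappa = kappa, m = m,
       parent_rates = parent_rates, parent_kappa = parent_kappa)
}

# direction of d* response to a single reduced efficacy: "lower", "raise",
# or NA when the probe system is degenerate
dstar_direction <- function(parent_rates, parent_kappa, axis, d_parent,
                            m_test = 0.6) {
  m <- trans_efficacy()
  m[axis] <- m_test
  sys <- symmetric_f1_system(parent_rates, parent_kappa, m)
  ss <- tryCatch(find_steady_state(sys), error = function(e) NULL)
  if (is.null(ss) || !ss$unique) return(NA_character_)
  dm <- tryCatch(as.numeric(critical_diffusion_ratio(sys, ss)),
                 error = function(e) NA_real_)
  if (is.na(dm)) return(NA_character_)
  if (is.finite(dm) && dm < d_parent) "lower" else "raise"
}

# modal single-axis response pattern required of a symmetric fixture parent
MODAL_DIRECTIONS <- c(uu = "raise", uv = "lower", vu = "lower", vv = "raise")

symmetric_parent_ok <- function(parent_rates, parent_kappa) {
  sysP <- symmetric_f1_system(parent_rates, parent_kappa)  # m = 1: parent
  ssP <- tryCatch(find_steady_state(sysP), error = function(e) NULL)
  if (is.null(ssP) || !ssP$unique)
    return("parent: no unique steady state")
  if (max_re_eig(reaction_jacobian(sysP, ssP$concentrations)) >= -STAB_MARGIN)
    return("parent: reaction Jacobian unstable")
  dP <- tryCatch(as.numeric(critical_diffusion_ratio(sysP, ssP)),
                 error = function(e) NA_real_)
  if (!is.finite(dP)) return("parent: no Turing bifurcation in bracket")
  dirs <- vapply(names(MODAL_DIRECTIONS), function(a)
    dstar_direction(parent_rates, parent_kappa, a, dP), "")
  if (any(is.na(dirs)) || any(dirs != MODAL_DIRECTIONS))
    return("parent: efficacy responses outside the modal regime")
  # the mechanism axis must respond cleanly: d*(m_vu) monotone over [0, 1]
  sw <- dstar_sweep(parent_rates, parent_kappa, "vu",
                    m_grid = seq(0, 1, by = 0.1))
  if (any(!is.finite(sw$d_star)) || any(diff(sw$d_star) <= 0))
    return("parent: d*(m_vu) not monotone")
  NULL
}

# rescale D_u so the fastest-growing mode of `system` at ratio d has
# wavelength `target` (in grid units of the default solver configuration)
calibrate_D_u <- function(system, steady_state, d, target = 12) {
  mg <- max_growth_rate(system, steady_state, d)
  lambda <- 2 * pi / mg$k_max
  system$D_u * (target / lambda)^2
}

#' Search for an admissible multigenerational parameter set
#'
#' Draws candidate parameter sets log-uniformly within `bounds` until one
#' passes [check_admissibility()]: unique stable steady states for both
#' parents and the F1 hybrid, with critical diffusion ratios ordered
#' `d*_F1 < min(d*_A, d*_B)`. The working ratio `d_used` is set to the
#' geometric mean of `d*_F1` and `min(d*_A, d*_B, d_cap)`, and `D_u` is then
#' rescaled so the F1's fastest-growing wavelength is about 12 length units,
#' convenient for the default simulation grid. Optionally every F2 genotype
#' is additionally required to have a unique stable steady state, so that
#' all nine phenotype simulations are well posed. The search is
#' deterministic given `seed`.
#'
#' @param seed Integer RNG seed.
#' @param bounds Sampling bounds, see [default_search_bounds()].
#' @param max_tries Maximum number of candidate draws.
#' @param mode `"general"` draws all 28 kinetic parameters independently;
#'   `"symmetric"` draws allele-independent parents plus four trans/cis
#'   efficacy ratios `m_**` (the identical-parents limit).
#' @param require_f2_unique Also require unique stable steady states for all
#'   nine F2 genotypes (default `TRUE`).
#' @param d_cap Upper cap for `d_used` when the parents' `d*` is infinite.
#' @return A list of class `mg_search_result`: `params` (with `D_u`, `D_v`
#'   set to the calibrated values so `D_v/D_u = d_used`), `report`, `tries`,
#'   `seed`, `mode`, and a `rejections` table of failure reasons.
#' @export
search_admissible <- function(seed, bounds = default_search_bounds(),
                              max_tries = 1000,
                              mode = c("general", "symmetric"),
                              require_f2_unique = TRUE, d_cap = 200) {
  mode <- match.arg(mode)
  set.seed(seed)
  rejections <- character()
  for (try in seq_len(max_tries)) {
    draw <- switch(mode,
                   general = draw_params_general(bounds),
                   symmetric = draw_params_symmetric(bounds))
    if (max(draw$kappa) <= 1.0000001 * min(draw$kappa)) {
      rejections <- c(rejections, "F1 identical to parents")
      next
    }
    if (mode == "symmetric") {
      bad <- symmetric_parent_ok(draw$parent_rates, draw$parent_kappa)
      if (!is.null(bad)) {
        rejections <- c(rejections, bad)
        next
      }
    }
    params <- mg_params(draw$rates, draw$kappa, D_u = 1, D_v = 2)
    core <- dstar_parents_f1(params)
    if (length(core$reasons)) {
      rejections <- c(rejections, core$reasons[1])
      next
    }
    rep0 <- list(d_star_A = core$dstar[["A"]], d_star_B = core$dstar[["B"]],
                 d_star_F1 = core$dstar[["F1"]])
    if (!is.finite(rep0$d_star_F1)) {
      rejections <- c(rejections, "F1: no Turing bifurcation in bracket")
      next
    }
    d_hi <- min(rep0$d_star_A, rep0$d_star_B, d_cap)
    if (!(rep0$d_star_F1 < d_hi)) {
      rejections <- c(rejections, "d_star_F1 >= min parent d_star")
      next
    }
    # demand a real gap so the F1 instability (and the parents' stability)
    # is robust rather than marginal, then sit d well inside it
    if (d_hi / rep0$d_star_F1 < 2.5) {
      rejections <- c(rejections, "insufficient d_star gap between F1 and parents")
      next
    }
    d_used <- rep0$d_star_F1 * min(2, sqrt(d_hi / rep0$d_star_F1))
    if (require_f2_unique && !all_f2_unique(params)) {
      rejections <- c(rejections, "an F2 genotype lacks a unique steady state")
      next
    }
    # calibrate diffusion scale to a convenient pattern wavelength
    f1 <- build_system(params, "U:AB,V:AB")
    ss <- find_steady_state(f1)
    D_u <- calibrate_D_u(f1, ss, d_used)
    params$D_u <- D_u
    params$D_v <- d_used * D_u
    report <- check_admissibility(params, d = d_used)
    if (!report$verdict) {  # numerically marginal ordering; keep searching
      rejections <- c(rejections, report$reasons[1])
      next
    }
    attr(params, "meta") <- c(list(seed = seed, try = try, mode = mode,
                                   d_used = d_used),
                              if (mode == "symmetric") list(m = as.list(draw$m)))
    return(structure(list(params = params, report = report, tries = try,
                          seed = seed, mode = mode,
                          rejections = table(rejections)),
                     class = "mg_search_result"))
  }
  stop("no admissible parameter set in ", max_tries, " tries; rejections: ",
       paste(sprintf("%s (%d)", names(table(rejections)), table(rejections)),
             collapse = ", "), call. = FALSE)
}

all_f2_unique <- function(params) {
  for (g in enumerate_f2()$genotype) {
    sys <- build_system(params, g)
    ss <- tryCatch(find_steady_state(sys), error = function(e) NULL)
    if (is.null(ss) || !ss$unique) return(FALSE)
    if (max_re_eig(reaction_jacobian(sys, ss$concentrations)) >= -STAB_MARGIN)
      return(FALSE)
  }
  TRUE
}

#' @export
print.mg_search_result <- function(x, ...) {
  cat(sprintf("admissible parameter set found at try %d (seed %d, %s mode)\n",
              x$tries, x$seed, x$mode))
  print(x$report)
  invisible(x)
}
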