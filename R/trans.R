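# Symmetric-parents limit: parents share allele-independent rate constants
# and cis binding constants; the F1 hybrid differs only through trans/cis
# binding-efficacy ratios m_** = kappa_trans / kappa_cis, 0 <= m < 1 when
# trans binding is the weaker. In total-concentration variables
# (ub = u + uh, vb = v + vh) the doubly heterozygous F1 contracts exactly to
# a two-species system with effective binding constants kappa (1 + m) / 2
# and production terms 2 alpha, 2 gamma; m = 1 recovers the contracted
# parent system.

#' Construct a trans/cis efficacy vector
#'
#' @param m_uu,m_uv,m_vu,m_vv Ratios of trans to cis binding constants for
#'   the four regulatory interactions (first index: regulated TF; second:
#'   binding TF). All default to 1 (parents).
#' @return Named numeric vector of class `trans_efficacy`.
#' @export
trans_efficacy <- function(m_uu = 1, m_uv = 1, m_vu = 1, m_vv = 1) {
  m <- c(uu = m_uu, uv = m_uv, vu = m_vu, vv = m_vv)
  if (any(!is.finite(m)) || any(m < 0))
    stop("efficacy ratios must be finite and >= 0", call. = FALSE)
  structure(m, class = "trans_efficacy")
}

#' Two-species F1 system in the symmetric-parents limit
#'
#' Builds the contracted (total-concentration) reaction system for the F1
#' hybrid of phenotypically identical parents. The parents are described by
#' allele-independent rate constants and four cis binding constants; the F1
#' differs only in that trans binding is scaled by the efficacy ratios
#' `m_**`. On the symmetric manifold `u = uh`, `v = vh`, the four-species
#' system reduces exactly to two species with effective binding constants
#' `kappa_** (1 + m_**) / 2`, baseline production `2 alpha`, regulated
#' production `2 gamma`, and unchanged degradation. Setting every `m_** = 1`
#' recovers the contracted parent system.
#'
#' @param parent_rates Named list with entries `u` and `v`, each
#'   `c(alpha=, beta=, gamma=)` (allele-independent parent kinetics).
#' @param parent_kappa Named numeric vector `c(uu=, uv=, vu=, vv=)` of cis
#'   binding constants.
#' @param m A [trans_efficacy()] vector (or coercible named vector).
#' @param D_u,D_v Diffusion coefficients.
#' @return A 2-species `reaction_system` (species `ub`, `vb`), with the
#'   genotype marked `U:AB,V:AB`.
#' @export
symmetric_f1_system <- function(parent_rates, parent_kappa,
                                m = trans_efficacy(), D_u = 1, D_v = 20) {
  m <- do.call(trans_efficacy, as.list(setNames(as.numeric(m[c("uu", "uv",
                                                               "vu", "vv")]),
                                                paste0("m_", c("uu", "uv",
                                                               "vu", "vv")))))
  keff <- parent_kappa[c("uu", "uv", "vu", "vv")] *
    (1 + m[c("uu", "uv", "vu", "vv")]) / 2
  ru <- unlist(parent_rates$u); rv <- unlist(parent_rates$v)
  KU <- matrix(c(keff["uu"], 0, keff["vu"], 0), 2, 2, byrow = TRUE)
  KV <- matrix(c(0, keff["uv"], 0, keff["vv"]), 2, 2, byrow = TRUE)
  kk <- matrix(c("uu_AA", "uv_AA", "vu_AA", "vv_AA"), 2, 2, byrow = TRUE)
  dimnames(KU) <- dimnames(KV) <- dimnames(kk) <-
    list(regulated = c("ub", "vb"), binding = c("ub", "vb"))
  new_reaction_system(
    species = c("ub", "vb"), tf = c("u", "v"), allele = c("A", "A"),
    alpha = 2 * c(ru[["alpha"]], rv[["alpha"]]),
    beta = c(ru[["beta"]], rv[["beta"]]),
    gamma = 2 * c(ru[["gamma"]], rv[["gamma"]]),
    KU = KU, KV = KV, kappa_keys = kk,
    D_u = D_u, D_v = D_v, genotype = mg_genotype("AB", "AB"),
    mult = c(2, 2))
}

#' Expand symmetric-parent parameters to a full multigenerational set
#'
#' Builds the 16-entry binding table from four cis constants and four
#' efficacy ratios: `kappa^AA = kappa^BB = kappa_cis` and
#' `kappa^AB = kappa^BA = m * kappa_cis`; rate constants are copied to both
#' alleles.
#'
#' @inheritParams symmetric_f1_system
#' @return A `mg_params` object.
#' @export
symmetric_params <- function(parent_rates, parent_kappa,
                             m = trans_efficacy(), D_u = 1, D_v = 20) {
  rates <- lapply(setNames(nm = rate_keys()), function(k)
    unlist(parent_rates[[substr(k, 1, 1)]])[c("alpha", "beta", "gamma")])
  kappa <- setNames(numeric(16), kappa_keys())
  for (key in kappa_keys()) {
    pair <- substr(key, 1, 2)
    cis_pair <- substr(key, 4, 5) %in% c("AA", "BB")
    kappa[key] <- parent_kappa[[pair]] * if (cis_pair) 1 else
      as.numeric(m[[pair]])
  }
  mg_params(rates, kappa, D_u = D_u, D_v = D_v)
}

#' Critical diffusion ratio as a function of one trans efficacy
#'
#' Sweeps a single efficacy ratio `m_**` over `m_grid` (the other three held
#' at 1) and records the critical diffusion ratio of the resulting
#' symmetric F1 system. Grid points where the system has no Turing
#' bifurcation in the bracket are recorded as `Inf`; points where the
#' steady state is non-unique or the reaction Jacobian unstable are `NA`.
#'
#' @inheritParams symmetric_f1_system
#' @param which Which efficacy to vary: `"uu"`, `"uv"`, `"vu"`, or `"vv"`.
#' @param m_grid Grid of efficacy values (default 41 points on \[0, 1\]).
#' @param d_bracket Bracket for [critical_diffusion_ratio()].
#' @return Data frame with columns `m` and `d_star`.
#' @export
dstar_sweep <- function(parent_rates, parent_kappa,
                        which = c("uu", "uv", "vu", "vv"),
                        m_grid = seq(0, 1, length.out = 41),
                        d_bracket = c(1, 1e4)) {
  which <- match.arg(which)
  d_star <- vapply(m_grid, function(mi) {
    m <- trans_efficacy()
    m[which] <- mi
    sys <- symmetric_f1_system(parent_rates, parent_kappa, m)
    ss <- tryCatch(find_steady_state(sys), error = function(e) NULL)
    if (is.null(ss) || !ss$unique) return(NA_real_)
    tryCatch(as.numeric(critical_diffusion_ratio(sys, ss, d_bracket)),
             error = function(e) NA_real_)
  }, 0)
  data.frame(m = m_grid, d_star = d_star)
}
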