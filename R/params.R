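#' @importFrom stats runif setNames sd optimize fft
#' @importFrom utils write.csv
NULL

# canonical orderings used throughout
TFS <- c("u", "v")
ALLELES <- c("A", "B")

#' The 16 binding-constant keys
#'
#' Names follow the table convention used for diploid binding constants:
#' the first subscript pair is the regulated transcription factor and its
#' allele, the second pair is the binding transcription factor and its allele.
#' `"uv_AB"` is the association constant for the allele-B inhibitor binding
#' the regulatory site of the allele-A activator.
#'
#' @return Character vector of the 16 keys in canonical order.
#' @export
kappa_keys <- function() {
  as.vector(vapply(TFS, function(rt)
    vapply(TFS, function(bt)
      vapply(ALLELES, function(ra)
        vapply(ALLELES, function(ba)
          paste0(rt, bt, "_", ra, ba), ""), character(2)), character(4)),
    character(8)))
}

#' The four per-allele rate-constant keys
#'
#' One entry per (transcription factor, allele) pair, e.g. `"u_A"` for the
#' allele-A activator gene product.
#'
#' @return Character vector of length 4.
#' @export
rate_keys <- function() {
  as.vector(outer(TFS, ALLELES, function(t, a) paste0(t, "_", a)))
}

#' Construct a multigenerational parameter set
#'
#' A `mg_params` object is the complete heritable parameterization of one
#' simulated cross: per-allele rate constants (baseline production `alpha`,
#' first-order degradation `beta`, maximal regulated production `gamma`) for
#' the activator and inhibitor gene products, the 16 competitive-binding
#' association constants, and the two diffusion coefficients. Concentration
#' units are arbitrary; each `kappa * concentration` product is dimensionless.
#'
#' @param rates Named list with entries `u_A`, `u_B`, `v_A`, `v_B`, each a
#'   named numeric vector or list with elements `alpha`, `beta`, `gamma`.
#' @param kappa Named numeric vector with the 16 keys of [kappa_keys()],
#'   all values `>= 0`.
#' @param D_u,D_v Diffusion coefficients (length^2/time) for activator and
#'   inhibitor gene products; independent of allele. Pattern formation
#'   requires `D_v > D_u`.
#' @return An object of class `mg_params`.
#' @export
mg_params <- function(rates, kappa, D_u, D_v) {
  p <- structure(list(rates = rates, kappa = kappa, D_u = D_u, D_v = D_v),
                 class = "mg_params")
  validate_params(p)
}

#' Validate a multigenerational parameter set
#'
#' Checks completeness (4 rate triples, 16 binding constants) and sign
#' constraints (`alpha`, `beta` strictly positive; `gamma`, `kappa`
#' nonnegative; positive diffusion coefficients). Error messages name the
#' offending key.
#'
#' @param p An `mg_params` object or a bare list with the same fields.
#' @return The validated object, invisibly classed `mg_params`.
#' @export
validate_params <- function(p) {
  for (k in rate_keys()) {
    r <- p$rates[[k]]
    if (is.null(r)) stop("missing rate entry '", k, "'", call. = FALSE)
    r <- unlist(r)
    for (nm in c("alpha", "beta", "gamma"))
      if (is.null(r[[nm]]) || !is.finite(r[[nm]]))
        stop("rate entry '", k, "' lacks finite '", nm, "'", call. = FALSE)
    if (r[["alpha"]] <= 0) stop("alpha of '", k, "' must be > 0", call. = FALSE)
    if (r[["beta"]] <= 0) stop("beta of '", k, "' must be > 0", call. = FALSE)
    if (r[["gamma"]] < 0) stop("gamma of '", k, "' must be >= 0", call. = FALSE)
    p$rates[[k]] <- r[c("alpha", "beta", "gamma")]
  }
  kk <- kappa_keys()
  miss <- setdiff(kk, names(p$kappa))
  if (length(miss))
    stop("missing binding constant(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  kv <- unlist(p$kappa)[kk]
  if (any(!is.finite(kv)) || any(kv < 0))
    stop("binding constants must be finite and >= 0; offending key(s): ",
         paste(kk[!is.finite(kv) | kv < 0], collapse = ", "), call. = FALSE)
  p$kappa <- kv
  if (!is.finite(p$D_u) || p$D_u <= 0) stop("D_u must be > 0", call. = FALSE)
  if (!is.finite(p$D_v) || p$D_v <= 0) stop("D_v must be > 0", call. = FALSE)
  class(p) <- "mg_params"
  p
}

#' Read a parameter set from JSON
#'
#' Schema: `{"rates": {"u_A": {"alpha": ..., "beta": ..., "gamma": ...},
#' ...}, "kappa": {"uu_AA": ..., 16 keys}, "D_u": ..., "D_v": ...}`.
#' Any additional top-level fields (e.g. search provenance) are preserved in
#' the `"meta"` attribute.
#'
#' @param path Path to a JSON file.
#' @return A validated `mg_params` object.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- validate_params(list(rates = as.list(x$rates),
                            kappa = unlist(x$kappa),
                            D_u = x$D_u, D_v = x$D_v))
  extra <- setdiff(names(x), c("rates", "kappa", "D_u", "D_v"))
  if (length(extra)) attr(p, "meta") <- x[extra]
  p
}

#' Write a parameter set to JSON
#'
#' Writes the canonical serialization read by [load_params()]. Keys are
#' emitted in canonical order so that save/load round-trips are
#' byte-identical.
#'
#' @param p A `mg_params` object.
#' @param path Output path.
#' @param meta Optional named list of provenance fields (seed, try index,
#'   chosen diffusion ratio) stored alongside the parameters.
#' @return `path`, invisibly.
#' @export
save_params <- function(p, path, meta = attr(p, "meta")) {
  p <- validate_params(p)
  out <- list(
    rates = lapply(setNames(nm = rate_keys()), function(k) as.list(p$rates[[k]])),
    kappa = as.list(p$kappa[kappa_keys()]),
    D_u = p$D_u, D_v = p$D_v)
  if (!is.null(meta)) out <- c(out, meta)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.mg_params <- function(x, ...) {
  cat("Multigenerational parameter set (2 loci x 2 alleles)\n")
  r <- do.call(rbind, lapply(x$rates[rate_keys()], unlist))
  print(round(r, 4))
  cat("kappa (16 binding constants):\n")
  print(round(x$kappa, 4))
  cat(sprintf("D_u = %g, D_v = %g (d = D_v/D_u = %g)\n",
              x$D_u, x$D_v, x$D_v / x$D_u))
  invisible(x)
}

# log-uniform draw helper
runif_log <- function(n, lo, hi) 10^runif(n, log10(lo), log10(hi))
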