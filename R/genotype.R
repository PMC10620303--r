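#' Construct a two-locus diploid genotype
#'
#' A genotype holds the diploid state at the two unlinked loci: `U`
#' (activator) and `V` (inhibitor), each `"AA"`, `"AB"`, or `"BB"`. The
#' heterozygote is unordered (`"BA"` is normalized to `"AB"`); within a
#' heterozygous locus, haplotype 1 carries allele A and haplotype 2 allele B.
#'
#' @param U,V Locus states, each one of `"AA"`, `"AB"`, `"BB"` (or `"BA"`).
#' @return An object of class `mg_genotype`.
#' @examples
#' mg_genotype("AB", "BB")
#' parse_genotype("U:AB,V:BB")
#' @export
mg_genotype <- function(U, V) {
  norm <- function(g, locus) {
    g <- toupper(g)
    if (g == "BA") g <- "AB"
    if (!g %in% c("AA", "AB", "BB"))
      stop("invalid state '", g, "' at locus ", locus, call. = FALSE)
    g
  }
  structure(list(U = norm(U, "U"), V = norm(V, "V")), class = "mg_genotype")
}

#' @rdname mg_genotype
#' @param x For `parse_genotype`, a string in the format `"U:AB,V:BB"`.
#' @export
parse_genotype <- function(x) {
  if (inherits(x, "mg_genotype")) return(x)
  m <- regmatches(x, regexec("^U:([ABab]{2}),V:([ABab]{2})$", x))[[1]]
  if (length(m) != 3)
    stop("cannot parse genotype '", x, "' (expected \"U:AB,V:BB\")",
         call. = FALSE)
  mg_genotype(m[2], m[3])
}

#' @export
format.mg_genotype <- function(x, ...) sprintf("U:%s,V:%s", x$U, x$V)

#' @export
print.mg_genotype <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# alleles carried by the two haplotypes at one locus
locus_alleles <- function(state) strsplit(state, "")[[1]]

is_homozygous <- function(state) {
  a <- locus_alleles(state)
  a[1] == a[2]
}

# per-locus gamete frequencies: P(transmit allele)
gamete_freq <- function(state) {
  a <- locus_alleles(state)
  tab <- table(factor(a, levels = c("A", "B"))) / 2
  as.numeric(tab)  # c(P(A), P(B))
}

# offspring locus-state distribution for one locus of a selfing
locus_cross <- function(state) {
  g <- gamete_freq(state)
  # genotype probabilities from two independent gametes; AB unordered
  p <- c(AA = g[1]^2, AB = 2 * g[1] * g[2], BB = g[2]^2)
  p[p > 0]
}

#' Enumerate the genotypes of a selfing cross
#'
#' Given a (possibly heterozygous) parent genotype, returns the distinct
#' offspring genotypes of a selfing with their Mendelian probabilities,
#' assuming independent segregation at the two unlinked loci. Selfing the
#' doubly heterozygous F1 yields the 9 distinct F2 genotypes with
#' probabilities \{1,2,1\} x \{1,2,1\} / 16.
#'
#' @param parent A `mg_genotype` (or genotype string); default the F1
#'   `"U:AB,V:AB"`.
#' @return A data frame with columns `genotype` (string form), `U`, `V`, and
#'   `prob`, probabilities summing to 1.
#' @export
enumerate_f2 <- function(parent = mg_genotype("AB", "AB")) {
  parent <- parse_genotype(parent)
  pu <- locus_cross(parent$U)
  pv <- locus_cross(parent$V)
  out <- data.frame(U = rep(names(pu), times = length(pv)),
                    V = rep(names(pv), each = length(pu)),
                    prob = as.vector(outer(pu, pv)),
                    stringsAsFactors = FALSE)
  out$genotype <- sprintf("U:%s,V:%s", out$U, out$V)
  out[, c("genotype", "U", "V", "prob")]
}

#' Resolve the parameter subset used by one genotype
#'
#' Maps each of the (up to four) gene-product species of a genotype to its
#' allele-resolved rate constants, and each Hill-term interaction to its
#' binding-constant key: every rate constant gets the superscript of its own
#' allele, every binding constant the (regulated allele, binding allele)
#' pair. Homozygous loci reference only same-allele superscripts at that
#' locus.
#'
#' @param genotype A `mg_genotype` or genotype string.
#' @param params A `mg_params` object (the full F1 parameterization).
#' @return A list with `rate_keys` (named by species), `kappa_keys` (matrix
#'   of Table-style keys, rows = regulated species, cols = binding species),
#'   and the corresponding numeric values.
#' @export
assign_parameters <- function(genotype, params) {
  genotype <- parse_genotype(genotype)
  params <- validate_params(params)
  au <- locus_alleles(genotype$U)
  av <- locus_alleles(genotype$V)
  species <- c("u", "v", "uh", "vh")
  tf <- c("u", "v", "u", "v")
  allele <- c(au[1], av[1], au[2], av[2])
  rk <- setNames(paste0(tf, "_", allele), species)
  kk <- outer(seq_along(species), seq_along(species), function(i, j)
    paste0(tf[i], tf[j], "_", allele[i], allele[j]))
  dimnames(kk) <- list(regulated = species, binding = species)
  list(rate_keys = rk,
       kappa_keys = kk,
       rates = lapply(rk, function(k) params$rates[[k]]),
       kappa = matrix(params$kappa[kk], 4, 4, dimnames = dimnames(kk)))
}

#' Count distinct binding constants referenced by a genotype
#'
#' The number of distinct binding-constant table entries appearing in the
#' genotype's contracted reaction terms: 4 for doubly homozygous genotypes,
#' 9 for singly heterozygous, 16 for the doubly heterozygous F1.
#'
#' @inheritParams assign_parameters
#' @param params Optional `mg_params`; only key bookkeeping is used.
#' @return Integer count of distinct keys.
#' @export
count_kappa <- function(genotype, params = NULL) {
  genotype <- parse_genotype(genotype)
  asg <- assign_parameters(genotype, params %||% .dummy_params())
  keep <- rep(TRUE, 4)
  if (is_homozygous(genotype$U)) keep[3] <- FALSE  # uh merged into u
  if (is_homozygous(genotype$V)) keep[4] <- FALSE  # vh merged into v
  length(unique(as.vector(asg$kappa_keys[keep, keep])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# unit-valued parameter set for pure key bookkeeping
.dummy_params <- function() {
  mg_params(rates = lapply(setNames(nm = rate_keys()), function(k)
    c(alpha = 1, beta = 1, gamma = 1)),
    kappa = setNames(rep(1, 16), kappa_keys()),
    D_u = 1, D_v = 20)
}
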