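#' Parse a multi-locus genotype string
#'
#' Genotypes are written `"Locus=allele1/allele2"` separated by commas, e.g.
#' `"Ezh2=fl/+,Cre=cre/0,Mmp9=-/-"`. A hemizygous transgene is modelled as a
#' locus with a null allele (`cre/0`). In target genotypes the wildcard
#' allele `*` matches anything (`Cre=cre/*` means "carries at least one cre
#' allele").
#'
#' @param x A genotype string, or a named list of length-2 character vectors
#'   (returned unchanged after validation).
#' @return A named list: locus -> character vector of two allele symbols.
#' @examples
#' parse_genotype("Ezh2=fl/+,Cre=cre/0")
#' @export
parse_genotype <- function(x) {
  if (is.list(x)) {
    ok <- length(x) > 0 && !is.null(names(x)) && all(nzchar(names(x))) &&
      all(vapply(x, function(a) is.character(a) && length(a) == 2 && all(nzchar(a)),
                 logical(1)))
    if (!ok) abort("genotype list must map locus names to two non-empty allele symbols")
    return(x)
  }
  if (!is.character(x) || length(x) != 1L || !nzchar(x)) {
    abort("genotype must be a single string like \"Ezh2=fl/+,Cre=cre/0\"")
  }
  parts <- strsplit(trimws(strsplit(x, ",", fixed = TRUE)[[1]]), "=", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 2L, logical(1))
  if (any(bad)) abort(paste0("cannot parse genotype fragment: ",
                             vapply(parts[bad], paste, "", collapse = "=")[1]))
  loci <- vapply(parts, `[[`, "", 1L)
  alleles <- lapply(parts, function(p) {
    al <- strsplit(p[[2]], "/", fixed = TRUE)[[1]]
    if (length(al) != 2L || !all(nzchar(al))) {
      abort(paste0("locus ", p[[1]], ": genotype must be two alleles separated by '/'"))
    }
    al
  })
  setNames(alleles, loci)
}

match_allele <- function(pattern, allele) pattern == "*" | pattern == allele

locus_target_probability <- function(sire, dam, target) {
  p <- 0
  for (s in sire) {
    for (d in dam) {
      hit <- (match_allele(target[1], s) && match_allele(target[2], d)) ||
        (match_allele(target[1], d) && match_allele(target[2], s))
      if (hit) p <- p + 0.25
    }
  }
  p
}

#' Expected Mendelian fraction of a target genotype
#'
#' Computes the probability that a random offspring of the specified cross
#' carries the target alleles, assuming independent assortment of loci and
#' uniform segregation of each parent's two alleles. Loci omitted from the
#' target are unconstrained; within a locus the wildcard `*` matches any
#' allele. A target allele carried by neither parent simply yields
#' fraction 0.
#'
#' For the rescue cross of `Ezh2 fl/+; Cre cre/0; Mmp9 -/+` sires with
#' `Ezh2 fl/fl; Cre 0/0; Mmp9 -/-` dams, the conditional-knockout,
#' Mmp9-null genotype (`Ezh2=fl/fl, Cre=cre/*, Mmp9=-/-`) is expected in
#' 1/2 x 1/2 x 1/2 = 12.5% of offspring, and the conditional knockout
#' pooled over Mmp9 (`Ezh2=fl/fl, Cre=cre/*`) in 25%.
#'
#' @param sire,dam Parental genotypes ([parse_genotype()] input).
#' @param target Target genotype; may use `*` wildcards and omit loci.
#' @return Expected offspring fraction in `[0, 1]`.
#' @examples
#' mendelian_expected_fraction(
#'   sire = "Ezh2=fl/+,Cre=cre/0,Mmp9=-/+",
#'   dam = "Ezh2=fl/fl,Cre=0/0,Mmp9=-/-",
#'   target = "Ezh2=fl/fl,Cre=cre/*,Mmp9=-/-"
#' )
#' @export
mendelian_expected_fraction <- function(sire, dam, target) {
  sire <- parse_genotype(sire)
  dam <- parse_genotype(dam)
  target <- parse_genotype(target)
  missing <- setdiff(names(target), intersect(names(sire), names(dam)))
  if (length(missing)) {
    abort(paste0("target locus absent from a parental genotype: ",
                 paste(missing, collapse = ", ")))
  }
  prod(vapply(names(target), function(l) {
    locus_target_probability(sire[[l]], dam[[l]], target[[l]])
  }, numeric(1)))
}

#' Full offspring genotype distribution of a cross
#'
#' Enumerates every distinct (unordered) offspring genotype of the cross
#' and its expected Mendelian fraction. Fractions sum to 1.
#'
#' @inheritParams mendelian_expected_fraction
#' @return A tibble with one column per locus (genotype written
#'   `"x/y"` with alleles sorted) and a `fraction` column.
#' @export
mendelian_genotype_distribution <- function(sire, dam) {
  sire <- parse_genotype(sire)
  dam <- parse_genotype(dam)
  loci <- intersect(names(sire), names(dam))
  if (!setequal(names(sire), names(dam))) {
    abort("sire and dam must specify the same loci")
  }
  per_locus <- lapply(loci, function(l) {
    combos <- expand.grid(s = sire[[l]], d = dam[[l]], stringsAsFactors = FALSE)
    geno <- vapply(seq_len(nrow(combos)), function(i) {
      paste(sort(c(combos$s[i], combos$d[i])), collapse = "/")
    }, "")
    stats::aggregate(list(p = rep(0.25, length(geno))), by = list(geno = geno), FUN = sum)
  })
  grid <- expand.grid(lapply(per_locus, function(d) seq_len(nrow(d))))
  out <- as_tibble(setNames(
    lapply(seq_along(loci), function(j) per_locus[[j]]$geno[grid[[j]]]),
    loci
  ))
  out$fraction <- apply(grid, 1, function(ix) {
    prod(vapply(seq_along(loci), function(j) per_locus[[j]]$p[ix[j]], numeric(1)))
  })
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by enumeration of all tables compatible with the
#' observed margins: the hypergeometric probabilities of all tables no more
#' probable than the observed one (up to a 1e-7 relative tolerance for
#' floating-point ties) are summed. The reported odds ratio is the sample
#' (cross-product) odds ratio `ad / bc`.
#'
#' @param counts A 2x2 matrix of non-negative integers, or a length-4
#'   vector in row-major order (a, b, c, d).
#' @return A list: `odds_ratio`, `p`, `degenerate` (TRUE with a warning and
#'   NA results when a margin is zero), `method`.
#' @examples
#' fisher_exact_2x2(c(5, 5, 5, 5))$p   # 1: perfect independence
#' @export
fisher_exact_2x2 <- function(counts) {
  if (is.matrix(counts)) {
    if (!all(dim(counts) == c(2L, 2L))) abort("`counts` must be 2x2")
    m <- counts
  } else {
    if (length(counts) != 4L) abort("`counts` must have 4 cells")
    m <- matrix(as.numeric(counts), nrow = 2, byrow = TRUE)
  }
  if (any(m < 0) || any(m != trunc(m))) abort("`counts` must be non-negative integers")
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  row1 <- a + b; row2 <- c_ + d; col1 <- a + c_; col2 <- b + d
  if (min(row1, row2, col1, col2) == 0) {
    warn("a margin of the 2x2 table is zero; the exact test is undefined")
    return(list(odds_ratio = NA_real_, p = NA_real_, degenerate = TRUE,
                method = "sample odds ratio"))
  }
  support <- max(0, col1 - row2):min(row1, col1)
  probs <- dhyper(support, row1, row2, col1)
  p_obs <- dhyper(a, row1, row2, col1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c_)
  }
  list(odds_ratio = or, p = p, degenerate = FALSE, method = "sample odds ratio")
}
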