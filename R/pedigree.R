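#' Simulate a family-structured cohort
#'
#' Generates a pedigree of nuclear families (two founders plus children),
#' a requested number of monozygotic (MZ) twin pairs placed among the
#' children, and a set of unrelated singletons, together with the expected
#' additive kinship matrix derived from the pedigree.
#'
#' The kinship matrix is on the additive-relationship scale used by the
#' mixed model downstream: self = 1, MZ co-twin = 1 (identical genomes),
#' parent-offspring = 0.5, full siblings = 0.5, members of different
#' families = 0. No inbreeding is modeled, so the diagonal is exactly 1.
#'
#' @param n_families Number of nuclear families.
#' @param family_size_range Length-2 integer vector, inclusive range of
#'   family sizes (2 = childless couple; size - 2 children otherwise).
#' @param n_twin_pairs Number of MZ twin pairs to place; requires at least
#'   this many families with >= 2 children.
#' @param n_unrelated Number of unrelated singleton individuals appended.
#' @param seed Integer seed; all randomness in this function flows from it.
#' @return List with `pedigree` (data.frame: id, father, mother, family,
#'   twin_group; NA father/mother for founders, NA twin_group for
#'   non-twins) and `kinship` (named symmetric matrix).
#' @export
simulate_pedigree <- function(n_families = 56L, family_size_range = c(2L, 14L),
                              n_twin_pairs = 25L, n_unrelated = 377L,
                              seed = 1L) {
  stopifnot(n_families >= 0, n_twin_pairs >= 0, n_unrelated >= 0,
            length(family_size_range) == 2, family_size_range[1] >= 2,
            family_size_range[2] >= family_size_range[1])
  set.seed(seed)
  sizes <- integer(0)
  if (n_families > 0) {
    lo <- family_size_range[1]; hi <- family_size_range[2]
    # small families are much more common than large ones
    pr <- 2^(-(lo:hi))
    sizes <- sample(lo:hi, n_families, replace = TRUE, prob = pr / sum(pr))
    # twin pairs need families with >= 2 children (size >= 4)
    n_capable <- sum(sizes >= 4)
    if (n_twin_pairs > n_capable) {
      need <- n_twin_pairs - n_capable
      small <- which(sizes < 4)
      if (length(small) < need)
        stop("n_twin_pairs exceeds family capacity for ", n_families,
             " families", call. = FALSE)
      sizes[small[seq_len(need)]] <- 4L
    }
  } else if (n_twin_pairs > 0) {
    stop("n_twin_pairs exceeds family capacity (no families)", call. = FALSE)
  }

  id <- character(0); father <- character(0); mother <- character(0)
  family <- character(0); twin_group <- character(0)
  capable <- which(sizes >= 4)
  twin_fams <- if (n_twin_pairs > 0)
    capable[sample.int(length(capable), n_twin_pairs)] else integer(0)
  for (f in seq_len(n_families)) {
    fam <- sprintf("F%03d", f)
    pa <- sprintf("%s_P1", fam); ma <- sprintf("%s_P2", fam)
    id <- c(id, pa, ma); father <- c(father, NA, NA); mother <- c(mother, NA, NA)
    family <- c(family, fam, fam); twin_group <- c(twin_group, NA, NA)
    n_kids <- sizes[f] - 2L
    if (n_kids > 0) {
      kids <- sprintf("%s_C%02d", fam, seq_len(n_kids))
      tg <- rep(NA_character_, n_kids)
      if (f %in% twin_fams) tg[1:2] <- sprintf("%s_TW", fam)
      id <- c(id, kids); father <- c(father, rep(pa, n_kids))
      mother <- c(mother, rep(ma, n_kids))
      family <- c(family, rep(fam, n_kids)); twin_group <- c(twin_group, tg)
    }
  }
  if (n_unrelated > 0) {
    unr <- sprintf("U%04d", seq_len(n_unrelated))
    id <- c(id, unr); father <- c(father, rep(NA, n_unrelated))
    mother <- c(mother, rep(NA, n_unrelated))
    family <- c(family, sprintf("UF%04d", seq_len(n_unrelated)))
    twin_group <- c(twin_group, rep(NA, n_unrelated))
  }
  ped <- data.frame(id = id, father = father, mother = mother,
                    family = family, twin_group = twin_group,
                    stringsAsFactors = FALSE)
  list(pedigree = ped, kinship = kinship_from_pedigree(ped))
}

#' Additive kinship matrix from a pedigree
#'
#' Tabular-method additive relationship matrix (self = 1, parent-offspring
#' = 0.5), with MZ twins treated as carrying the same genome so their
#' mutual entry is 1 and they relate identically to everyone else.
#'
#' @param pedigree data.frame with columns id, father, mother, twin_group.
#' @return Symmetric matrix with dimnames = individual ids.
#' @export
kinship_from_pedigree <- function(pedigree) {
  stopifnot(all(c("id", "father", "mother") %in% names(pedigree)))
  ped <- pedigree
  if (is.null(ped$twin_group)) ped$twin_group <- NA_character_
  # collapse MZ twins onto one genome: the first member of each twin group
  genome <- ped$id
  for (tg in unique(stats::na.omit(ped$twin_group))) {
    mem <- ped$id[!is.na(ped$twin_group) & ped$twin_group == tg]
    genome[ped$id %in% mem] <- mem[1]
  }
  gped <- unique(data.frame(id = genome,
                            father = ped$father, mother = ped$mother,
                            stringsAsFactors = FALSE))
  if (anyDuplicated(gped$id))
    stop("MZ twins must share both parents", call. = FALSE)
  # order so parents precede children
  ord <- character(0); remaining <- gped
  while (nrow(remaining) > 0) {
    ready <- (is.na(remaining$father) | remaining$father %in% ord) &
             (is.na(remaining$mother) | remaining$mother %in% ord)
    if (!any(ready)) stop("pedigree is cyclic or has missing parents",
                          call. = FALSE)
    ord <- c(ord, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  gped <- gped[match(ord, gped$id), ]
  m <- nrow(gped)
  A <- matrix(0, m, m, dimnames = list(gped$id, gped$id))
  for (i in seq_len(m)) {
    fa <- gped$father[i]; mo <- gped$mother[i]
    if (i > 1) {
      prev <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (!is.na(fa)) v <- v + 0.5 * A[prev, fa]
      if (!is.na(mo)) v <- v + 0.5 * A[prev, mo]
      A[prev, i] <- A[i, prev] <- v
    }
    A[i, i] <- 1  # no inbreeding modeled
  }
  K <- A[genome, genome]
  dimnames(K) <- list(ped$id, ped$id)
  K
}

#' Deterministic unrelated subset
#'
#' One individual per family (the smallest id lexicographically), used for
#' Hardy-Weinberg testing and variant filtering so family structure does
#' not distort genotype-frequency tests.
#'
#' @param pedigree data.frame with columns id, family.
#' @return Character vector of ids.
#' @export
unrelated_subset <- function(pedigree) {
  sp <- split(pedigree$id, pedigree$family)
  sort(vapply(sp, function(x) sort(x)[1], character(1)), method = "radix")
}
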