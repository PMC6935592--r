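#' SNP quality control
#'
#' Filters a dosage matrix marker-by-marker on call rate, minor-allele
#' frequency and the per-locus fixation index
#' `F_IS = 1 - H_obs / H_exp`, with `H_exp = 2 p (1 - p)` computed from the
#' sample allele frequency over non-missing calls. A marker is kept when
#' call rate >= `call_rate_min`, MAF >= `maf_min` and `|F_IS| < fis_max_abs`
#' (monomorphic markers have an undefined `F_IS` and are removed by the MAF
#' rule).
#'
#' @param genotypes Dosage matrix in \{0, 1, 2, NA\}, individuals x markers.
#' @param call_rate_min,maf_min,fis_max_abs QC thresholds; the defaults are
#'   the usual array-panel settings (0.90, 0.005, 0.50).
#' @return A list with `genotypes` (kept markers only) and `report`, a tibble
#'   with per-marker `call_rate`, `maf`, `fis`, `kept` and `reason`.
#' @export
qc_filter <- function(genotypes, call_rate_min = 0.90, maf_min = 0.005,
                      fis_max_abs = 0.50) {
  stopifnot(is.matrix(genotypes), call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 0.5, fis_max_abs > 0)
  n <- nrow(genotypes)
  n_obs <- colSums(!is.na(genotypes))
  call_rate <- n_obs / n
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  p[n_obs == 0] <- NA_real_
  maf <- pmin(p, 1 - p)
  h_obs <- colMeans(genotypes == 1L, na.rm = TRUE)
  h_exp <- 2 * p * (1 - p)
  fis <- ifelse(h_exp > 0, 1 - h_obs / h_exp, NA_real_)
  kept <- !is.na(call_rate) & call_rate >= call_rate_min &
    !is.na(maf) & maf >= maf_min &
    !is.na(fis) & abs(fis) < fis_max_abs
  reason <- rep(NA_character_, length(kept))
  reason[!kept] <- dplyr::case_when(
    call_rate[!kept] < call_rate_min ~ "call_rate",
    is.na(maf[!kept]) | maf[!kept] < maf_min ~ "maf",
    TRUE ~ "fis"
  )
  report <- tibble::tibble(
    marker = colnames(genotypes) %||% as.character(seq_len(ncol(genotypes))),
    call_rate = unname(call_rate), maf = unname(maf), fis = unname(fis),
    kept = unname(kept), reason = reason)
  if (!any(kept)) warning("all markers removed by QC", call. = FALSE)
  list(genotypes = genotypes[, kept, drop = FALSE], report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Impute missing genotypes with an LD-informed k-nearest-neighbour vote
#'
#' For each marker with missing calls, the `n_linked` markers most correlated
#' (squared Pearson r over pairwise-complete dosages) with the target marker
#' define a local metric; each missing call is filled with the plurality
#' dosage among the `k` individuals nearest in r2-weighted Manhattan distance
#' over those markers (ties broken toward the smaller dosage). When fewer than `k`
#' usable neighbours exist (or no linked markers can be ranked), the call
#' falls back to the marker's mean dosage rounded to the nearest integer.
#' This is a simplified re-statement of the LD-kNNi idea used for array
#' panels; it is intentionally not a reimplementation of any specific tool.
#'
#' @inheritParams qc_filter
#' @param k Number of nearest neighbours in the vote.
#' @param n_linked Number of most-correlated markers defining the distance.
#' @return The dosage matrix with no remaining `NA`.
#' @export
impute_ld_knn <- function(genotypes, k = 5L, n_linked = 20L) {
  stopifnot(is.matrix(genotypes), k >= 1, n_linked >= 1)
  if (!anyNA(genotypes)) return(genotypes)
  G <- genotypes
  miss_marker <- which(colSums(is.na(G)) > 0)
  # squared correlation between markers, pairwise-complete
  suppressWarnings(R2 <- cor(G, use = "pairwise.complete.obs")^2)
  mean_dose <- round(colMeans(G, na.rm = TRUE))
  mean_dose[is.nan(mean_dose)] <- 0L
  for (j in miss_marker) {
    r2 <- R2[, j]
    r2[j] <- NA
    linked <- order(r2, decreasing = TRUE, na.last = TRUE)
    linked <- linked[!is.na(r2[linked])][seq_len(min(n_linked, sum(!is.na(r2))))]
    miss_i <- which(is.na(G[, j]))
    donors <- which(!is.na(genotypes[, j]))
    if (length(linked) == 0 || length(donors) < k) {
      G[miss_i, j] <- mean_dose[j]
      next
    }
    L <- genotypes[, linked, drop = FALSE]
    w <- r2[linked]
    for (i in miss_i) {
      dif <- abs(sweep(L[donors, , drop = FALSE], 2L, L[i, ]))
      wm <- matrix(w, nrow(dif), ncol(dif), byrow = TRUE)
      wm[is.na(dif)] <- NA
      d <- rowSums(dif * wm, na.rm = TRUE) / rowSums(wm, na.rm = TRUE)
      d[is.nan(d)] <- Inf
      usable <- which(is.finite(d))
      if (length(usable) < k) { G[i, j] <- mean_dose[j]; next }
      nn <- donors[usable[order(d[usable])][seq_len(k)]]
      votes <- tabulate(genotypes[nn, j] + 1L, nbins = 3L)
      G[i, j] <- which.max(votes) - 1L  # which.max takes the first (smallest dosage) on ties
    }
  }
  G
}

#' Pedigree-based numerator relationship matrix
#'
#' Computes Wright's numerator relationship matrix A by the recursive tabular
#' method over a topologically ordered pedigree: founders are unrelated and
#' non-inbred; for individual i with parents s and d,
#' `A[i, j] = (A[s, j] + A[d, j]) / 2` for previous j and
#' `A[i, i] = 1 + A[s, d] / 2`.
#'
#' @param pedigree Tibble with columns `id`, `sire`, `dam` (`NA` for unknown).
#' @return Symmetric PSD matrix indexed by individual id.
#' @export
compute_A <- function(pedigree) {
  stopifnot(all(c("id", "sire", "dam") %in% names(pedigree)))
  if (anyDuplicated(pedigree$id)) stop("duplicated ids in pedigree", call. = FALSE)
  ord <- pedigree_order(pedigree)
  ped <- pedigree[ord, ]
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  s_idx <- match(ped$sire, ped$id)
  d_idx <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    si <- s_idx[i]; di <- d_idx[i]
    if (is.na(si) && is.na(di)) {
      A[i, i] <- 1
    } else {
      prev <- seq_len(i - 1L)
      row_s <- if (is.na(si)) rep(0, i - 1L) else A[si, prev]
      row_d <- if (is.na(di)) rep(0, i - 1L) else A[di, prev]
      if (i > 1L) {
        A[i, prev] <- 0.5 * (row_s + row_d)
        A[prev, i] <- A[i, prev]
      }
      A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) 0.5 * A[si, di] else 0
    }
  }
  A[pedigree$id, pedigree$id]
}

# topological order of a pedigree; errors on cycles naming the ids involved
pedigree_order <- function(pedigree) {
  n <- nrow(pedigree)
  id <- pedigree$id
  s <- match(pedigree$sire, id)
  d <- match(pedigree$dam, id)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed &
                     (is.na(s) | placed[ifelse(is.na(s), 1L, s)]) &
                     (is.na(d) | placed[ifelse(is.na(d), 1L, d)]))
    if (length(ready) == 0) break
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  if (length(ord) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(id[!placed], collapse = ", "), call. = FALSE)
  }
  ord
}

#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum_j p_j (1 - p_j))` with `Z = M - 2p` the
#' column-centred dosage matrix and `p` the sample allele frequencies of the
#' supplied (post-QC, imputed) panel.
#'
#' @param genotypes Complete dosage matrix (no `NA`); run [impute_ld_knn()]
#'   first.
#' @param p Optional vector of allele frequencies to centre on; defaults to
#'   the sample frequencies of the supplied panel.
#' @return Symmetric matrix indexed by individual id.
#' @export
compute_G <- function(genotypes, p = NULL) {
  stopifnot(is.matrix(genotypes))
  if (anyNA(genotypes)) stop("genotypes contain missing calls; impute first",
                             call. = FALSE)
  if (is.null(p)) p <- colMeans(genotypes) / 2
  stopifnot(length(p) == ncol(genotypes))
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers are monomorphic: VanRaden denominator is zero",
                       call. = FALSE)
  Z <- sweep(genotypes, 2L, 2 * p)
  tcrossprod(Z) / denom
}

#' Verify a recorded pedigree against genomic relationships
#'
#' Compares A and G over their shared individuals: reports the Pearson
#' correlation of all off-diagonal entries, and flags any individual whose
#' mean absolute discordance `|G - A|` with its recorded first-degree
#' relatives (entries with `A >= 0.5` off the diagonal, i.e. parents and full
#' sibs) exceeds `discord_threshold`. A mislabelled tree is genomically
#' unrelated to its recorded family, so its discordance is about 0.5 while
#' correctly recorded trees sit near the Mendelian-sampling noise level.
#'
#' @param A,G Relationship matrices sharing (a superset of) the same ids.
#' @param discord_threshold Mean `|G - A|` above which a tree is flagged.
#' @return A list with `pearson_r`, `flagged` (character ids) and
#'   `discordance`, a tibble of per-individual mean discordances.
#' @export
verify_pedigree <- function(A, G, discord_threshold = 0.35) {
  ids <- intersect(rownames(A), rownames(G))
  if (length(ids) < 2) stop("A and G share fewer than two ids", call. = FALSE)
  A <- A[ids, ids]; G <- G[ids, ids]
  off <- upper.tri(A)
  r <- cor(A[off], G[off])
  disc <- vapply(seq_along(ids), function(i) {
    rel <- which(A[i, ] >= 0.5)
    rel <- setdiff(rel, i)
    if (length(rel) == 0) return(NA_real_)
    mean(abs(G[i, rel] - A[i, rel]))
  }, numeric(1))
  out <- tibble::tibble(id = ids, mean_discordance = disc,
                        flagged = !is.na(disc) & disc > discord_threshold)
  list(pearson_r = r, flagged = out$id[out$flagged], discordance = out)
}
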