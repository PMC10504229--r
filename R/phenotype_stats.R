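## phenotype_stats: trait summaries, Pearson correlations, subgroup
## t-tests and top-accession mining for multi-trait tables.

## half-up rounding to `digits` decimals, used only for display totals
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Per-trait summary statistics
#'
#' Missing values are excluded per trait; `n` reports the number of
#' non-missing observations. `sd` is `NA` for fewer than two values.
#'
#' @param traits a `trait_table`.
#' @return `data.frame` with columns `trait`, `mean`, `sd`, `min`,
#'   `max`, `n`.
#' @export
summarize_traits <- function(traits) {
  tm <- trait_matrix(traits)
  if (nrow(tm) < 1) stop("empty trait table")
  do.call(rbind, lapply(colnames(tm), function(tr) {
    x <- tm[, tr]
    x <- x[!is.na(x)]
    data.frame(trait = tr,
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               min = if (length(x)) min(x) else NA_real_,
               max = if (length(x)) max(x) else NA_real_,
               n = length(x), stringsAsFactors = FALSE)
  }))
}

#' Pairwise Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations with two-sided t-based
#' p-values. Pairs with fewer than 3 complete observations, or with a
#' constant member, get `NA` (flagged through the `n` matrix).
#'
#' @param traits a `trait_table`.
#' @return list of trait x trait matrices: `r`, `p`, `n`.
#' @export
correlation_matrix <- function(traits) {
  tm <- trait_matrix(traits)
  k <- ncol(tm)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(tm), colnames(tm)))
  n <- matrix(0L, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- stats::complete.cases(tm[, i], tm[, j])
      nn <- sum(ok)
      n[i, j] <- n[j, i] <- nn
      if (nn < 3) next
      x <- tm[ok, i]; y <- tm[ok, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      rr <- stats::cor(x, y)
      r[i, j] <- r[j, i] <- rr
      if (i == j) {
        p[i, j] <- 0
      } else {
        tt <- rr * sqrt((nn - 2) / max(1 - rr^2, .Machine$double.eps))
        p[i, j] <- p[j, i] <- 2 * stats::pt(abs(tt), nn - 2,
                                            lower.tail = FALSE)
      }
    }
  }
  list(r = r, p = p, n = n)
}

#' Student's t-test per trait between two subgroups
#'
#' Two-sided pooled-variance (classical Student) t-test of each trait
#' between the two subgroup labels. A trait is untestable when either
#' subgroup has fewer than two non-missing values.
#'
#' @param traits a `trait_table`.
#' @param labels named vector (names = accession ids) with exactly two
#'   distinct values.
#' @return `data.frame` with columns `trait`, `group1`, `group2`,
#'   `n1`, `n2`, `t`, `df`, `p_value`, `untestable`.
#' @export
subgroup_ttest <- function(traits, labels) {
  tm <- trait_matrix(traits)
  labels <- labels[intersect(names(labels), rownames(tm))]
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) stop("labels must define exactly two subgroups")
  do.call(rbind, lapply(colnames(tm), function(tr) {
    x <- tm[names(labels)[labels == lv[1]], tr]
    y <- tm[names(labels)[labels == lv[2]], tr]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    rec <- data.frame(trait = tr, group1 = lv[1], group2 = lv[2],
                      n1 = length(x), n2 = length(y), t = NA_real_,
                      df = NA_real_, p_value = NA_real_,
                      untestable = TRUE, stringsAsFactors = FALSE)
    if (length(x) >= 2 && length(y) >= 2 &&
        (stats::sd(x) > 0 || stats::sd(y) > 0)) {
      ht <- stats::t.test(x, y, var.equal = TRUE)
      rec$t <- unname(ht$statistic)
      rec$df <- unname(ht$parameter)
      rec$p_value <- ht$p.value
      rec$untestable <- FALSE
    } else if (length(x) >= 2 && length(y) >= 2) {
      ## both constant and equal -> no difference by construction
      rec$t <- 0; rec$df <- length(x) + length(y) - 2; rec$p_value <- 1
      rec$untestable <- FALSE
    }
    rec
  }))
}

#' Top accessions per trait
#'
#' For each trait, the `k` accessions with the highest content are
#' selected (ties at rank `k` keep all tied accessions). Reports the
#' union of selected accessions, each member's total content (sum over
#' all traits, with a display version rounded half-up to 2 decimals)
#' and the number of traits in which it ranks top-`k`.
#'
#' @param traits a `trait_table`.
#' @param k how many accessions per trait (default 5).
#' @return list: `top` (named list per trait of accession ids,
#'   descending content), `union` (accession ids sorted by descending
#'   total), `report` (`data.frame` with `accession_id`, `total`,
#'   `total_display`, `n_traits_top`).
#' @export
top_accessions <- function(traits, k = 5) {
  tm <- trait_matrix(traits)
  if (k > nrow(tm)) stop("k exceeds number of accessions")
  top <- lapply(colnames(tm), function(tr) {
    x <- tm[, tr]
    x <- x[!is.na(x)]
    if (length(x) == 0) return(character(0))
    xs <- sort(x, decreasing = TRUE)
    thr <- xs[min(k, length(xs))]
    sel <- x[x >= thr]
    names(sel)[order(-sel, match(names(sel), rownames(tm)))]
  })
  names(top) <- colnames(tm)
  members <- unique(unlist(top))
  totals <- rowSums(tm[members, , drop = FALSE], na.rm = TRUE)
  n_top <- vapply(members, function(a)
    sum(vapply(top, function(v) a %in% v, logical(1))), integer(1))
  ord <- order(-totals)
  report <- data.frame(accession_id = members[ord],
                       total = unname(totals[ord]),
                       total_display = round_half_up(unname(totals[ord]), 2),
                       n_traits_top = unname(n_top[ord]),
                       stringsAsFactors = FALSE)
  list(top = top, union = report$accession_id, report = report)
}
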