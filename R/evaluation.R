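#' A method's pathway ranking
#'
#' Light container for comparing enrichment methods: the full ordered
#' pathway list (best first) and the subset called significant.
#'
#' @param method method name.
#' @param ranking character vector of pathway identifiers, rank 1 first;
#'   no duplicates.
#' @param significant character vector of significant pathway identifiers;
#'   must be a subset of `ranking`.
#' @return an object of class `method_ranking`.
#' @export
method_ranking <- function(method, ranking, significant = character()) {
  ranking <- as.character(ranking)
  if (anyDuplicated(ranking)) {
    stop("ranking contains duplicate identifiers", call. = FALSE)
  }
  significant <- as.character(significant)
  if (!all(significant %in% ranking)) {
    stop("significant set must be a subset of the ranking", call. = FALSE)
  }
  structure(
    list(method = as.character(method), ranking = ranking,
         significant = significant),
    class = "method_ranking"
  )
}

#' Coerce to a method ranking
#'
#' @param x object to coerce; for an `enrichment_result` the rank order
#'   and significance flags are taken from the table.
#' @param ... unused.
#' @return a [method_ranking()].
#' @export
as_method_ranking <- function(x, ...) UseMethod("as_method_ranking")

#' @rdname as_method_ranking
#' @export
as_method_ranking.enrichment_result <- function(x, ...) {
  md <- attr(x, "metadata")
  ord <- order(x$rank)
  method_ranking(
    method = if (!is.null(md$method)) md$method else "unknown",
    ranking = x$pathway_id[ord],
    significant = x$pathway_id[x$significant]
  )
}

#' @rdname as_method_ranking
#' @export
as_method_ranking.method_ranking <- function(x, ...) x

#' Significance-overlap agreement between two methods
#'
#' Compares the significant pathway sets called by two methods on the same
#' candidate collection: the common count, the Jaccard-style ratio of
#' common to total unique significant pathways, and the upper-tail
#' hypergeometric p-value of observing at least that overlap when
#' `|sig_b|` pathways are drawn from a background of `background`
#' candidates containing `|sig_a|` successes.
#'
#' @param sig_a,sig_b significant pathway identifier sets (character
#'   vectors, or `method_ranking`s whose `significant` slot is used).
#' @param background total number of candidate pathways; must be at least
#'   the union size.
#' @return list with `common`, `ratio` (`NA` when both sets are empty) and
#'   `p_value`.
#' @export
overlap_significance <- function(sig_a, sig_b, background) {
  if (inherits(sig_a, "method_ranking")) sig_a <- sig_a$significant
  if (inherits(sig_b, "method_ranking")) sig_b <- sig_b$significant
  sig_a <- unique(as.character(sig_a))
  sig_b <- unique(as.character(sig_b))
  uni <- union(sig_a, sig_b)
  if (background < length(uni)) {
    stop("background (", background,
         ") smaller than the union of significant sets (", length(uni), ")",
         call. = FALSE)
  }
  common <- length(intersect(sig_a, sig_b))
  list(
    common = common,
    ratio = if (length(uni) > 0L) common / length(uni) else NA_real_,
    p_value = phyper(common - 1, length(sig_a),
                     background - length(sig_a), length(sig_b),
                     lower.tail = FALSE)
  )
}

#' Spearman rank correlation between two method rankings
#'
#' Both rankings must cover exactly the same pathway identifiers; ties (not
#' possible in a strict ordering, but allowed when rank vectors are passed
#' downstream) are handled by the usual average-rank convention.
#'
#' @param r1,r2 [method_ranking()]s over the same identifier set.
#' @return Spearman's rho.
#' @export
rank_correlation <- function(r1, r2) {
  r1 <- as_method_ranking(r1)
  r2 <- as_method_ranking(r2)
  if (!setequal(r1$ranking, r2$ranking)) {
    stop("rankings cover different pathway identifier sets", call. = FALSE)
  }
  ids <- r1$ranking
  cor(match(ids, r1$ranking), match(ids, r2$ranking), method = "spearman")
}

#' Positive and negative cross verification of a ranking
#'
#' For the focal method's `top_k` pathways, counts how many are also
#' top-`top_k` in other methods (positive verification — corroborated
#' calls) and how many fall below rank `deep_k` in *all* other methods
#' (negative verification — likely spurious calls). The positive count
#' uses `"any"` mode by default (endorsed by at least one other method);
#' `"all"` requires endorsement by every other method. A pathway missing
#' from another method's ranking counts as ranked below `deep_k` there.
#'
#' @param focal a [method_ranking()].
#' @param others list of `method_ranking`s to verify against.
#' @param top_k size of the head compared (default 20).
#' @param deep_k depth below which a pathway counts as negative
#'   (default 100); every ranking must reach this depth, and
#'   `top_k < deep_k`.
#' @param mode `"any"` or `"all"` for the positive count.
#' @return named integer vector `c(positive = ..., negative = ...)`;
#'   positive + negative never exceeds `top_k`.
#' @export
cross_verification <- function(focal, others, top_k = 20L, deep_k = 100L,
                               mode = c("any", "all")) {
  mode <- match.arg(mode)
  focal <- as_method_ranking(focal)
  others <- lapply(others, as_method_ranking)
  if (length(others) == 0L) stop("need at least one other method", call. = FALSE)
  if (!(top_k < deep_k)) stop("top_k must be < deep_k", call. = FALSE)
  lens <- c(length(focal$ranking), vapply(others, function(o)
    length(o$ranking), integer(1)))
  if (any(lens < deep_k)) {
    stop("every ranking must contain at least deep_k = ", deep_k,
         " pathways", call. = FALSE)
  }
  top_f <- focal$ranking[seq_len(top_k)]
  in_top <- vapply(others, function(o) {
    top_f %in% o$ranking[seq_len(top_k)]
  }, logical(length(top_f)))
  in_top <- matrix(in_top, nrow = length(top_f))
  below <- vapply(others, function(o) {
    r <- match(top_f, o$ranking)
    is.na(r) | r > deep_k
  }, logical(length(top_f)))
  below <- matrix(below, nrow = length(top_f))
  positive <- if (mode == "any") {
    sum(apply(in_top, 1L, any))
  } else {
    sum(apply(in_top, 1L, all))
  }
  c(positive = positive, negative = sum(apply(below, 1L, all)))
}

#' @export
print.method_ranking <- function(x, ...) {
  cat("method_ranking (", x$method, "): ", length(x$ranking),
      " pathways, ", length(x$significant), " significant\n", sep = "")
  invisible(x)
}
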