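#' Read gene sets from a GMT file
#'
#' Parses the tab-separated MSigDB distribution format: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' set are collapsed; lines with no genes are skipped with a warning.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors, class `gene_set_collection`,
#'   with attribute `source`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(f) < 3L || length(genes) == 0L) {
      warning("skipping malformed GMT line: ", substr(ln, 1, 40))
      next
    }
    sets[[f[1]]] <- genes
  }
  if (length(sets) == 0L) stop("no parseable gene sets in ", path)
  structure(sets, class = "gene_set_collection", source = basename(path))
}

#' Write gene sets to a GMT file
#'
#' @param collection named list of gene id vectors.
#' @param path output path.
#' @param descriptions optional descriptions (default "na").
#' @return the path, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(collection))
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(collection), descriptions, collection)
  writeLines(unname(lines), path)
  invisible(path)
}

# order genes by statistic descending, gene id as deterministic tie-break
rank_order <- function(stats_vec) {
  order(-stats_vec, names(stats_vec), method = "radix")
}

# ES from hit positions in the sorted list (walk evaluated only at hits:
# the running sum is piecewise linear between hits, so the signed maximal
# deviation is attained at a hit peak or just before a hit). Candidates
# are scanned in list order so |ES| ties resolve exactly as the full walk's
# which.max does.
es_from_positions <- function(pos, absw, n_total) {
  m <- length(pos)
  pos <- sort(pos)
  hitw <- absw[pos]
  denom <- sum(hitw)
  inc <- if (denom > 0) hitw / denom else rep(1 / m, m)
  miss <- 1 / (n_total - m)
  H <- cumsum(inc)
  top <- H - (pos - seq_len(m)) * miss              # value at hit j (pos_j)
  bot <- c(0, H[-m]) - (pos - seq_len(m)) * miss    # value at pos_j - 1
  cp <- c(pos - 1L, pos)
  cv <- c(bot, top)
  keep <- cp >= 1L
  cp <- cp[keep]; cv <- cv[keep]
  o <- order(cp)
  cv <- cv[o]
  cv[which.max(abs(cv))]
}

#' Running-sum enrichment score of a gene set in a ranked list
#'
#' Genes are sorted by the statistic in decreasing order (ties broken by
#' gene id). Walking down the list, hits increment the running sum by
#' `|stat|^weight / sum(hits |stat|^weight)` and misses decrement it by
#' `1/(N - N_hits)`. The enrichment score (ES) is the running-sum value of
#' maximal absolute deviation from zero (signed); the leading edge is the
#' set of hits at or before a positive extremum (at or after, for a
#' negative one).
#'
#' @param ranked named numeric vector: gene -> ranking statistic (finite).
#' @param gene_set character vector of gene ids.
#' @param weight exponent on `|stat|` for hit increments (default 1; 0
#'   gives the unweighted Kolmogorov-Smirnov-style walk).
#' @return list with `es`, `running` (full running sum in ranked order),
#'   `leading_edge`, and `hit_positions`.
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  if (any(!is.finite(ranked))) stop("ranking statistics must be finite")
  ord <- rank_order(ranked)
  sorted <- ranked[ord]
  genes <- names(sorted)
  hit <- genes %in% gene_set
  m <- sum(hit)
  if (m == 0L) stop("gene set has empty intersection with the ranked universe")
  if (m == length(genes)) stop("gene set covers the whole universe")
  absw <- abs(sorted)^weight
  denom <- sum(absw[hit])
  inc <- numeric(length(genes))
  inc[hit] <- if (denom > 0) absw[hit] / denom else 1 / m
  inc[!hit] <- -1 / (length(genes) - m)
  running <- cumsum(inc)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  hp <- which(hit)
  leading <- if (es >= 0) genes[hp[hp <= i_max]] else genes[hp[hp >= i_max]]
  list(es = es, running = stats::setNames(running, genes),
       leading_edge = leading, hit_positions = hp)
}

# null ES values for sets of size m: exhaustive over all position
# combinations when feasible, otherwise Monte-Carlo gene sampling
null_es <- function(absw, n_total, m, n_perm) {
  n_comb <- choose(n_total, m)
  if (is.finite(n_comb) && n_comb <= n_perm) {
    combs <- utils::combn(n_total, m)
    apply(combs, 2, es_from_positions, absw = absw, n_total = n_total)
  } else {
    vapply(seq_len(n_perm), function(i)
      es_from_positions(sample.int(n_total, m), absw, n_total), 0)
  }
}

#' Preranked gene-set enrichment analysis
#'
#' For each eligible set (intersection with the ranked universe between
#' `min_size` and `max_size`) computes the running-sum ES, a permutation
#' p-value against null ES values from random same-size gene samples of the
#' universe (exhaustive enumeration of all position combinations when there
#' are no more than `n_perm` of them), and a normalized ES. With the
#' plus-one estimator, `p = (1 + #same-sign nulls at least as extreme) /
#' (1 + #same-sign nulls)` and `NES = ES / mean(|same-sign null ES|)`.
#' Benjamini-Hochberg adjustment is applied across emitted sets.
#'
#' @param ranked named numeric vector of ranking statistics (e.g. meta
#'   summary SMDs or survival z-scores).
#' @param collection a `gene_set_collection` (or named list of gene sets).
#' @param n_perm permutations per set (default 10000).
#' @param seed seed for the permutation null.
#' @param min_size,max_size set-size bounds after intersection with the
#'   universe (defaults 5 and 500).
#' @param weight running-sum weight, see [enrichment_score()].
#' @return data.frame with set, size, es, nes, p, p_bh, leading_edge
#'   (comma-joined); skipped sets are recorded in the `skipped` attribute
#'   with reasons.
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 10000L, seed = 1L,
                           min_size = 5L, max_size = 500L, weight = 1) {
  set.seed(as.integer(seed))
  if (n_perm < 100L) stop("n_perm must be at least 100")
  ord <- rank_order(ranked)
  sorted <- ranked[ord]
  absw <- abs(sorted)^weight
  N <- length(sorted)
  rows <- list(); skipped <- character(0)
  null_cache <- list()
  for (nm in names(collection)) {
    isect <- intersect(collection[[nm]], names(sorted))
    m <- length(isect)
    if (m < min_size) { skipped[nm] <- "below min_size"; next }
    if (m > max_size) { skipped[nm] <- "above max_size"; next }
    sc <- enrichment_score(ranked, isect, weight = weight)
    key <- as.character(m)
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <- null_es(absw, N, m, n_perm)
    nulls <- null_cache[[key]]
    same <- nulls * sign(sc$es) > 0
    n_same <- sum(same)
    p <- (1 + sum(abs(nulls[same]) >= abs(sc$es))) / (1 + n_same)
    nes <- if (n_same > 0) sc$es / mean(abs(nulls[same])) else NA_real_
    rows[[nm]] <- data.frame(set = nm, size = m, es = sc$es, nes = nes,
                             p = p,
                             leading_edge = paste(sc$leading_edge,
                                                  collapse = ","),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p = numeric(0),
                      leading_edge = character(0))
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("set", "size", "es", "nes", "p", "p_bh", "leading_edge")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
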