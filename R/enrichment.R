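## Fisher's-exact over-representation of differential proteins in
## annotation terms (GO/KEGG-style), computed generically against a
## user-supplied GMT file. One-sided hypergeometric upper tail, unadjusted
## P <= alpha by default; a BH column is emitted for transparency.

#' Read a GMT annotation file
#'
#' Standard tab-separated format: term id, description, then member ids.
#'
#' @param path GMT file.
#' @return named list of member id vectors; descriptions kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    message(sum(bad), " malformed GMT line(s) skipped")
    parts <- parts[!bad]
  }
  stop_if(length(parts) == 0L, "no usable GMT records in '%s'", path)
  terms <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(terms) <- vapply(parts, `[`, "", 1L)
  stop_if(anyDuplicated(names(terms)) > 0, "duplicate term ids in '%s'", path)
  attr(terms, "descriptions") <- stats::setNames(
    vapply(parts, `[`, "", 2L), names(terms))
  terms
}

#' Write annotation terms as GMT
#'
#' @param terms named list of member id vectors.
#' @param path output file.
#' @param descriptions optional named description vector; defaults to the
#'   term id.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(terms, "descriptions")
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(terms), names(terms))
  lines <- vapply(names(terms), function(id)
    paste(c(id, descriptions[[id]], terms[[id]]), collapse = "\t"), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Fisher's exact over-representation analysis
#'
#' For each term, tests whether the selected proteins overlap the term's
#' members more than expected under hypergeometric sampling from the
#' background universe: p = P(X >= k) with k the observed overlap, K the
#' term size within the background, n the selection size and N the
#' background size. Terms are intersected with the background before
#' testing; terms left with no background members are skipped with a
#' message. The background should be the set of quantifiable proteins in
#' the experiment, not the whole proteome.
#'
#' @param selected protein ids called differential (subset of
#'   `background`).
#' @param background the protein universe conditioned on detection.
#' @param terms named list of member id vectors (see [read_gmt()]).
#' @param alpha significance cutoff on the unadjusted one-sided p.
#' @return data frame sorted by ascending p (ties by term id): term_id,
#'   overlap_k, selected_n, term_K, background_N, p, p_adj (BH, for
#'   transparency; not used for `significant`), significant.
#' @export
fisher_enrich <- function(selected, background, terms, alpha = 0.05) {
  selected <- unique(selected)
  background <- unique(background)
  stop_if(length(selected) == 0L, "'selected' is empty")
  stop_if(length(background) == 0L, "'background' is empty")
  stop_if(!all(selected %in% background),
          "'selected' must be a subset of 'background'")
  alpha <- check_proportion(alpha, "alpha")

  members <- lapply(terms, intersect, background)
  usable <- lengths(members) > 0L
  if (any(!usable))
    message(sum(!usable), " term(s) with no background overlap skipped: ",
            paste(utils::head(names(terms)[!usable], 5), collapse = ", "))
  members <- members[usable]
  stop_if(length(members) == 0L, "no term overlaps the background")

  N <- length(background)
  n <- length(selected)
  K <- lengths(members)
  k <- vapply(members, function(m) length(intersect(selected, m)), 0L)
  ## upper tail P(X >= k) of Hypergeometric(N, K, n)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = names(members), overlap_k = as.integer(k),
                    selected_n = n, term_K = as.integer(K), background_N = N,
                    p = unname(p), p_adj = unname(bh_adjust(p)),
                    significant = unname(p <= alpha),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Comparative enrichment matrix across groups
#'
#' A term x group matrix of -log10 enrichment p-values, the data behind
#' shaded comparative-enrichment panels.
#'
#' @param enrich_by_group named list of [fisher_enrich()] outputs, one per
#'   group.
#' @return numeric matrix (terms x groups) of -log10(p).
#' @export
enrichment_matrix <- function(enrich_by_group) {
  all_terms <- sort(unique(unlist(lapply(enrich_by_group, `[[`, "term_id"))))
  m <- sapply(enrich_by_group, function(e)
    -log10(e$p[match(all_terms, e$term_id)]))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(enrich_by_group),
                                   dimnames = list(NULL,
                                                   names(enrich_by_group)))
  rownames(m) <- all_terms
  m
}
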