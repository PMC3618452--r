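#' Read pathway sets in GMT format
#'
#' One pathway per line: name, description, then member IDs, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of member IDs; descriptions
#'   kept as attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    stop_fmt("GMT line %d has fewer than 3 fields", bad[1])
  }
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "descriptions") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' Read a one-ID-per-line list (universe or query)
#'
#' @param path Text file, one molecule ID per line; blank lines and
#'   `#` comments ignored.
#' @return Character vector of unique IDs.
#' @export
read_id_list <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  unique(ids[nzchar(ids) & !startsWith(ids, "#")])
}

#' Pathway over-representation by Fisher's exact test
#'
#' For each pathway, counts the query IDs among its members and
#' computes the right-tailed hypergeometric probability of at least
#' that overlap when drawing `|query|` IDs from the universe — the
#' one-sided Fisher's exact p-value — plus the coverage ratio
#' `hits / |members in universe|`. Query IDs outside the universe are
#' dropped with a warning; pathways are intersected with the universe.
#'
#' @param query Character vector of molecule IDs of interest (e.g. KEGG
#'   compound IDs of treatment-related metabolites; protein IDs may be
#'   mixed in — IDs are opaque strings).
#' @param pathways Named list of member-ID vectors (see [read_gmt()]).
#' @param universe Character vector of all assayable IDs.
#' @param top_n Report the top pathways by ascending p-value
#'   (default 10); `Inf` reports all.
#' @return Data frame `pathway`, `hits`, `pathway_size`, `ratio`,
#'   `p_value`, `p_bh` (Benjamini-Hochberg adjusted, an optional
#'   extra), `query_size`, `universe_size`, sorted by ascending
#'   p-value.
#' @export
fisher_enrichment <- function(query, pathways, universe, top_n = 10) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe)) stop_fmt("universe is empty")
  if (!length(query)) stop_fmt("query is empty")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query ID(s) outside the universe dropped: %s",
                    length(outside),
                    paste(utils::head(outside, 5), collapse = ", ")),
            call. = FALSE)
    query <- intersect(query, universe)
    if (!length(query)) stop_fmt("no query IDs remain in the universe")
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(pathways), function(pw) {
    members <- intersect(unique(pathways[[pw]]), universe)
    K <- length(members)
    h <- length(intersect(query, members))
    p <- if (K == 0) 1 else
      stats::phyper(h - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, hits = h, pathway_size = K,
               ratio = if (K > 0) h / K else NA_real_,
               p_value = p, query_size = n, universe_size = N,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Recompute printed pathway coverage ratios
#'
#' Coverage ratio of a pathway: hit count divided by pathway size,
#' rounded to the precision at which it is reported.
#'
#' @param hits,size Integer vectors.
#' @param digits Decimal places of the reported value (default 3).
#' @return Numeric vector of rounded ratios.
#' @export
coverage_ratio <- function(hits, size, digits = 3) {
  round(hits / size, digits)
}

#' Published top-pathway table (hits, sizes, printed ratios)
#'
#' The reported IPA top canonical pathways for the MK-801 rat study
#' (cortex, hippocampus, and the metabolite+protein integrated
#' analysis) with printed Fisher p-values, hit counts, pathway sizes
#' and coverage ratios. The `consistent` flag marks rows whose printed
#' ratio agrees with the printed hits/size at the printed precision
#' (one cortex row is internally inconsistent as printed).
#'
#' @return Data frame with columns `analysis`, `pathway`, `p_printed`,
#'   `hits`, `size`, `ratio_printed`, `consistent`.
#' @export
published_pathway_table <- function() {
  read_table_commented(system.file("extdata", "ipa_top_pathways.tsv",
                                   package = "nmropls", mustWork = TRUE),
                       colClasses = c(ratio_printed = "character"))
}
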