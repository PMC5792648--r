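#' Locate reads on the anchor coordinate system
#'
#' Projects each read onto the ancestral (anchor) 16S sequence by best local
#' alignment (match +1, mismatch -1, gap -2, either strand). Because the
#' synthetic references are substitution-only derivatives of the anchor,
#' template coordinates coincide with anchor coordinates, so in
#' `truth_mode` the simulator's ground-truth intervals are used directly.
#'
#' @param sequences character vector of reads.
#' @param refset a `ReferenceSet`.
#' @param min_identity minimum identity over aligned columns to accept a
#'   location (anchor-level identity is lower than reference-level identity
#'   because hypervariable blocks diverge from the anchor).
#' @param min_aln_len minimum aligned columns.
#' @param truth_mode logical; use `truth` intervals instead of aligning.
#' @param truth optional data.frame with `start`, `end` columns (0-based
#'   half-open template intervals), row-aligned with `sequences`.
#' @return data.frame with `start`, `end` (anchor span, NA when unplaced)
#'   and `strand`.
#' @export
locate_on_anchor <- function(sequences, refset, min_identity = 0.6,
                             min_aln_len = 50, truth_mode = FALSE,
                             truth = NULL) {
  if (truth_mode) {
    stop_if_not(!is.null(truth), "truth_mode requires a truth table")
    return(data.frame(start = truth$start, end = truth$end,
                      strand = if ("strand" %in% names(truth)) truth$strand
                               else NA_character_))
  }
  n <- length(sequences)
  out <- data.frame(start = rep(NA_real_, n), end = NA_real_,
                    strand = NA_character_)
  if (n == 0L) return(out)
  score_pick <- function(aln) {
    nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
    span <- nm + nmm
    list(score = BiocGenerics::score(aln),
         ok = span >= min_aln_len & ifelse(span > 0, nm / span, 0) >= min_identity,
         start = BiocGenerics::start(Biostrings::subject(aln)) - 1L,
         end = BiocGenerics::end(Biostrings::subject(aln)))
  }
  af <- score_pick(local_align_batch(sequences, refset$anchor))
  ar <- score_pick(local_align_batch(rev_comp(sequences), refset$anchor))
  use_f <- af$score >= ar$score
  pick <- function(field) ifelse(use_f, af[[field]], ar[[field]])
  ok <- ifelse(use_f, af$ok, ar$ok)
  out$start[ok] <- pick("start")[ok]
  out$end[ok] <- pick("end")[ok]
  out$strand[ok] <- ifelse(use_f, "+", "-")[ok]
  out
}

#' Assign an anchor span to a hypervariable-region class
#'
#' Midpoint rule: the class whose interval contains `floor((start + end) /
#' 2)` (intervals 0-based half-open); spans whose midpoint falls in a
#' conserved gap get `"none"`.
#'
#' @param start,end numeric vectors: anchor spans (0-based half-open).
#' @param region_map data.frame with `class`, `start`, `end` (as in a
#'   `ReferenceSet`).
#' @return character vector of class labels (`"none"` when unbinned).
#' @export
assign_region <- function(start, end, region_map) {
  mid <- floor((start + end) / 2)
  out <- rep("none", length(mid))
  for (i in seq_len(nrow(region_map))) {
    inside <- !is.na(mid) & mid >= region_map$start[i] & mid < region_map$end[i]
    out[inside] <- region_map$class[i]
  }
  out[is.na(mid)] <- "none"
  out
}

#' Does a template fully cover the V4 region?
#'
#' True iff the template's best local alignment to the anchor covers the
#' whole V4 interval (the screen applied to assembled 16S sequences before
#' the in-silico PCR).
#'
#' @param template_seq template sequence.
#' @param refset a `ReferenceSet`.
#' @param min_identity,min_aln_len alignment acceptance thresholds.
#' @return logical.
#' @export
has_v4 <- function(template_seq, refset, min_identity = 0.6, min_aln_len = 50) {
  loc <- locate_on_anchor(template_seq, refset, min_identity, min_aln_len)
  if (is.na(loc$start[1])) return(FALSE)
  v4 <- refset$region_map[refset$region_map$class == "V4", ]
  loc$start[1] <= v4$start && loc$end[1] >= v4$end
}

#' Per-region classification report
#'
#' For every hypervariable-region class: the number of reads binned there,
#' the fraction of those reads assigned at each taxonomic rank (normalised
#' within the class), and the per-taxon counts at a chosen rank.
#'
#' @param regions data.frame with `read_id` and `class` (e.g. built with
#'   [assign_region()]).
#' @param classifications data.frame from [classify_reads()] (or any table
#'   keyed by `read_id` with the six rank columns).
#' @param rank rank for the per-taxon counts (default `"genus"`).
#' @return list with `summary` (class, n_reads, one `frac_<rank>` column per
#'   rank) and `taxa` (class, taxon, count).
#' @export
per_region_report <- function(regions, classifications, rank = "genus") {
  # the region bin column is renamed so it cannot collide with the "class"
  # taxonomic rank column of the classification table
  reg <- data.frame(read_id = regions$read_id, .region = regions$class,
                    stringsAsFactors = FALSE)
  merged <- merge(reg, classifications, by = "read_id")
  classes <- unique(reg$.region)
  classes <- c(sort(setdiff(classes, "none")), intersect("none", classes))
  summary_rows <- lapply(classes, function(cl) {
    sel <- merged[merged$.region == cl, , drop = FALSE]
    n <- nrow(sel)
    fr <- vapply(RANKS, function(r)
      if (n > 0) sum(!is.na(sel[[r]])) / n else 0, numeric(1L))
    cbind(data.frame(class = cl, n_reads = n),
          as.data.frame(as.list(setNames(fr, paste0("frac_", RANKS)))))
  })
  taxa_rows <- lapply(classes, function(cl) {
    sel <- merged[merged$.region == cl & !is.na(merged[[rank]]), , drop = FALSE]
    if (nrow(sel) == 0L)
      return(data.frame(class = character(0), taxon = character(0),
                        count = integer(0)))
    tab <- table(sel[[rank]])
    data.frame(class = cl, taxon = names(tab), count = as.integer(tab),
               row.names = NULL)
  })
  list(summary = do.call(rbind, summary_rows),
       taxa = do.call(rbind, taxa_rows))
}
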