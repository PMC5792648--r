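#' Default in-silico PCR matching parameters
#'
#' A template site is accepted when the primer's 3'-terminal
#' `three_prime_exact_len` bases match with zero mismatches and at most
#' `max_mismatches` mismatches occur elsewhere; a template passes when a
#' valid forward site lies upstream of a valid reverse site with a product
#' length inside `product_len`.
#'
#' @return list of matching parameters.
#' @export
default_match_params <- function() {
  list(max_mismatches = 3L, three_prime_exact_len = 9L,
       product_len = c(100L, 2000L))
}

#' IUPAC base matching
#'
#' Does a concrete template base fall inside the expansion of a degenerate
#' primer code? Vectorised over both arguments.
#'
#' @param template_base character vector of bases in `A,C,G,T`.
#' @param primer_code character vector of IUPAC codes.
#' @return logical vector.
#' @export
iupac_match <- function(template_base, primer_code) {
  stop_if_not(all(template_base %in% BASES), "template base must be one of A,C,G,T")
  stop_if_not(all(primer_code %in% names(Biostrings::IUPAC_CODE_MAP)),
              "invalid IUPAC code")
  mapply(function(b, cd) b %in% iupac_expand(cd), template_base, primer_code,
         USE.NAMES = FALSE)
}

# 4-bit mask per IUPAC code (bit 1=A, 2=C, 4=G, 8=T) for fast matching
iupac_mask <- function(codes) {
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  vapply(codes, function(cd) sum(bit[iupac_expand(cd)]), integer(1L))
}

#' Scan a template for degenerate-primer binding sites
#'
#' Slides the primer (for `orientation = "forward"`) or its reverse
#' complement (for `orientation = "reverse"`; the primer then anneals to the
#' minus strand, so its 3' end maps to the left edge of the plus-strand
#' site) along the template. A site is valid when the 3'-anchor bases match
#' exactly and the remaining positions carry at most `max_mismatches`
#' mismatches. Degenerate codes match every base of their expansion.
#'
#' @param template template sequence over A,C,G,T.
#' @param primer a primer as in [default_primer_pair()] (list with `name`,
#'   `seq`) or a plain IUPAC string.
#' @param params matching parameters, see [default_match_params()].
#' @param orientation `"forward"` or `"reverse"`.
#' @return data.frame with one row per valid site: `start`, `end` (0-based
#'   half-open on the template), `mismatches` (outside the anchor),
#'   `anchor_mismatches` (always 0 for valid sites).
#' @export
find_primer_sites <- function(template, primer, params = default_match_params(),
                              orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  pseq <- if (is.list(primer)) primer$seq else primer
  site_seq <- if (orientation == "forward") pseq else rev_comp(pseq)
  codes <- strsplit(site_seq, NULL)[[1L]]
  k <- length(codes)
  tb <- strsplit(template, NULL)[[1L]]
  stop_if_not(all(tb %in% BASES), "template must be over A,C,G,T")
  n <- length(tb)
  if (n < k) return(empty_sites())

  # the primer 3' anchor sits at the site's right edge for forward matches
  # and at the left edge for reverse (revcomp'd) matches
  a <- params$three_prime_exact_len
  stop_if_not(a <= k, "three_prime_exact_len exceeds primer length")
  anchor_pos <- if (orientation == "forward") (k - a + 1L):k else seq_len(a)

  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  tmask <- bit[tb]
  pmask <- iupac_mask(codes)
  n_off <- n - k + 1L
  mm_anchor <- integer(n_off)
  mm_other <- integer(n_off)
  for (j in seq_len(k)) {
    mism <- as.integer(bitwAnd(tmask[j:(j + n_off - 1L)], pmask[j]) == 0L)
    if (j %in% anchor_pos) mm_anchor <- mm_anchor + mism
    else mm_other <- mm_other + mism
  }
  ok <- mm_anchor == 0L & mm_other <= params$max_mismatches
  data.frame(start = which(ok) - 1L, end = which(ok) - 1L + k,
             mismatches = mm_other[ok], anchor_mismatches = mm_anchor[ok])
}

empty_sites <- function() {
  data.frame(start = integer(0), end = integer(0), mismatches = integer(0),
             anchor_mismatches = integer(0))
}

#' In-silico amplification of a template by a degenerate primer pair
#'
#' The template passes the virtual amplification when some valid forward
#' site lies strictly upstream of some valid reverse site and the resulting
#' product length (forward site start to reverse site end) falls within the
#' configured bounds. The shortest valid product is reported.
#'
#' @param template template sequence over A,C,G,T (plus-strand oriented).
#' @param fwd,rev primers (list with `name`, `seq`, or plain strings).
#' @param params matching parameters, see [default_match_params()].
#' @return list of class `PcrOutcome`: `pass` (logical), `fwd_site`,
#'   `rev_site`, `product` (each `c(start, end)` 0-based half-open, or NULL
#'   on failure) and `product_len`.
#' @export
virtual_pcr <- function(template, fwd, rev, params = default_match_params()) {
  fs <- find_primer_sites(template, fwd, params, "forward")
  rs <- find_primer_sites(template, rev, params, "reverse")
  best <- NULL
  if (nrow(fs) > 0 && nrow(rs) > 0) {
    for (i in seq_len(nrow(fs))) {
      for (j in seq_len(nrow(rs))) {
        if (fs$end[i] <= rs$start[j]) {
          len <- rs$end[j] - fs$start[i]
          if (len >= params$product_len[1] && len <= params$product_len[2] &&
              (is.null(best) || len < best$product_len)) {
            best <- list(fwd_site = c(fs$start[i], fs$end[i]),
                         rev_site = c(rs$start[j], rs$end[j]),
                         product = c(fs$start[i], rs$end[j]),
                         product_len = len)
          }
        }
      }
    }
  }
  out <- if (is.null(best)) {
    list(pass = FALSE, fwd_site = NULL, rev_site = NULL, product = NULL,
         product_len = NA_integer_)
  } else c(list(pass = TRUE), best)
  structure(out, class = "PcrOutcome")
}

#' Run virtual PCR over all references of a set
#'
#' @param refset a `ReferenceSet`.
#' @param params matching parameters.
#' @return data.frame with `taxon_id`, `pass`, `product_start`,
#'   `product_end`.
#' @export
virtual_pcr_refset <- function(refset, params = default_match_params()) {
  res <- lapply(refset$seqs, virtual_pcr, fwd = refset$primers$fwd,
                rev = refset$primers$rev, params = params)
  data.frame(taxon_id = refset$taxa$taxon_id,
             pass = vapply(res, `[[`, logical(1L), "pass"),
             product_start = vapply(res, function(r)
               if (r$pass) r$product[1] else NA_integer_, numeric(1L)),
             product_end = vapply(res, function(r)
               if (r$pass) r$product[2] else NA_integer_, numeric(1L)))
}

#' Summarise virtual-PCR failures per taxonomic group
#'
#' For each group at the requested rank, the number of templates failing the
#' virtual amplification is compared with the total number of templates in
#' the group, and expressed as a percentage (an overall row is appended).
#'
#' @param outcomes data.frame with logical column `pass` (e.g. from
#'   [virtual_pcr_refset()]), one row per template.
#' @param lineages data.frame with one row per template giving its lineage
#'   (columns as in [generate_taxonomy()]); row order matches `outcomes`.
#' @param rank rank at which to group (default `"phylum"`).
#' @param digits decimals for the reported percentage (1 by default; use 0
#'   for integer rounding).
#' @return data.frame `taxon`, `n_fail`, `n_total`, `percent`.
#' @export
failure_fraction_by_taxon <- function(outcomes, lineages, rank = "phylum",
                                      digits = 1) {
  stop_if_not(nrow(outcomes) == nrow(lineages),
              "outcomes and lineages must have one row per template")
  grp <- lineages[[rank]]
  keep <- !is.na(grp)
  tab <- aggregate(list(n_fail = !outcomes$pass[keep], n_total = rep(1L, sum(keep))),
                   by = list(taxon = grp[keep]), FUN = sum)
  tab <- rbind(tab, data.frame(taxon = "overall", n_fail = sum(!outcomes$pass),
                               n_total = nrow(outcomes)))
  tab$percent <- round(100 * tab$n_fail / tab$n_total, digits)
  tab[tab$n_total > 0, ]
}
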