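#' Restriction-cloning constants
#'
#' EcoRI (`G^AATTC`) and SalI (`G^TCGAC`) recognition sites with their
#' top-strand cut offset (both cut after the first base), the 6-nt primer
#' tail that pads the restriction site for efficient digestion, and the ITR
#' qPCR primer sequences used for rAAV titration fixtures.
#' @name cloning-constants
NULL

#' @rdname cloning-constants
#' @export
ECORI_SITE <- "GAATTC"

#' @rdname cloning-constants
#' @export
SALI_SITE <- "GTCGAC"

#' @rdname cloning-constants
#' @export
PRIMER_TAIL <- "GTGTAC"

#' @rdname cloning-constants
#' @export
ITR_PRIMER_FWD <- "CGGCCTCAGTGAGCGA"

#' @rdname cloning-constants
#' @export
ITR_PRIMER_REV <- "GGAACCCCTAGTGATGGAGTT"

# top-strand cut offset within both sites (G^AATTC, G^TCGAC)
CUT_OFFSET <- 1L

check_dna <- function(seq, allow_n = TRUE) {
  seq <- toupper(seq)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, seq)) stop("sequence contains characters outside A/C/G/T",
                             if (allow_n) "/N" else "")
  seq
}

#' Design EcoRI/SalI-flanked cloning primers
#'
#' Forward primer: 6-nt tail, EcoRI site, then the first `fwd_anchor_len`
#' bases of the enhancer. Reverse primer: 6-nt tail, SalI site, then the
#' reverse complement of the last `rev_anchor_len` bases. Anchor lengths
#' default to 22/26 nt, the lengths used for the vHC-20-72 construct.
#'
#' @param enhancer_seq enhancer sequence (5'->3', A/C/G/T).
#' @param fwd_anchor_len,rev_anchor_len genomic anchor lengths.
#' @return list of class `PrimerPair` with `forward`, `reverse` and a
#'   `structure` table (tail / site / anchor per primer).
#' @export
design_primers <- function(enhancer_seq, fwd_anchor_len = 22L,
                           rev_anchor_len = 26L) {
  seq <- check_dna(enhancer_seq)
  n <- nchar(seq)
  if (n <= fwd_anchor_len + rev_anchor_len)
    stop("enhancer too short for the requested anchors (", n, " bp)")
  fwd_anchor <- substr(seq, 1, fwd_anchor_len)
  rev_tail_genomic <- substr(seq, n - rev_anchor_len + 1, n)
  if (grepl("N", paste0(fwd_anchor, rev_tail_genomic)))
    stop("anchor contains N")
  rev_anchor <- revcomp(rev_tail_genomic)
  pp <- list(
    forward = paste0(PRIMER_TAIL, ECORI_SITE, fwd_anchor),
    reverse = paste0(PRIMER_TAIL, SALI_SITE, rev_anchor),
    structure = data.frame(
      primer = c("forward", "reverse"),
      tail = PRIMER_TAIL,
      site = c(ECORI_SITE, SALI_SITE),
      anchor = c(fwd_anchor, rev_anchor),
      stringsAsFactors = FALSE))
  class(pp) <- "PrimerPair"
  pp
}

#' Scan a sequence for restriction sites
#'
#' Reports every occurrence of each site on the given strand (0-based
#' positions). EcoRI and SalI sites are palindromic, so one strand suffices.
#' An empty result means the sequence is cloneable with these enzymes.
#'
#' @param seq A/C/G/T/N string.
#' @param sites character vector of recognition sequences.
#' @return data frame (`site`, `position`), 0-based; zero rows when clean.
#' @export
check_internal_sites <- function(seq, sites = c(ECORI_SITE, SALI_SITE)) {
  seq <- check_dna(seq)
  subject <- Biostrings::DNAString(seq)
  rows <- lapply(sites, function(s) {
    m <- Biostrings::matchPattern(s, subject)
    if (!length(m)) return(NULL)
    data.frame(site = s, position = Biostrings::start(m) - 1L,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(site = character(), position = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$position), , drop = FALSE]
}

# locate a primer anchor on the template; must match exactly once
locate_anchor <- function(anchor, template, label) {
  m <- Biostrings::matchPattern(anchor, Biostrings::DNAString(template))
  if (length(m) == 0)
    stop("no match for the ", label, " primer anchor on the template")
  if (length(m) > 1)
    stop("multiple matches (", length(m), ") for the ", label,
         " primer anchor on the template")
  c(start = Biostrings::start(m), end = Biostrings::end(m))
}

#' In-silico PCR
#'
#' Amplifies the template between the two primer anchors: the forward anchor
#' is matched on the top strand, the reverse anchor as its reverse complement
#' near the 3' end. The product is
#' `forward primer + template between/including anchors + revcomp(reverse
#' primer)`; for primers designed with [design_primers()] on the same
#' template this is the full enhancer flanked by tail+EcoRI and SalI+tail,
#' i.e. template length + 24.
#'
#' @param template template sequence.
#' @param primers a [design_primers()] pair.
#' @return the amplicon sequence (character string).
#' @export
in_silico_pcr <- function(template, primers) {
  stopifnot(inherits(primers, "PrimerPair"))
  template <- check_dna(template)
  fwd_anchor <- primers$structure$anchor[1]
  rev_anchor_on_template <- revcomp(primers$structure$anchor[2])
  f <- locate_anchor(fwd_anchor, template, "forward")
  r <- locate_anchor(rev_anchor_on_template, template, "reverse")
  if (r["end"] <= f["start"])
    stop("reverse anchor lies upstream of the forward anchor")
  inner <- substr(template, f["start"], r["end"])
  paste0(PRIMER_TAIL, ECORI_SITE, inner,
         SALI_SITE, revcomp(PRIMER_TAIL))
}

#' Synthetic reporter backbone
#'
#' Builds a synthetic plasmid backbone fixture for in-silico cloning: random
#' stuffer, an EcoRI/SalI polylinker, a 134-bp minimal promoter, a reporter
#' ORF and a polyadenylation signal. The promoter and all other segments are
#' synthetic placeholder sequences (random, scrubbed of stray EcoRI/SalI
#' sites); only the layout and the 134-bp promoter length are meaningful.
#'
#' @param seed integer seed.
#' @param promoter_len minimal-promoter length (134 bp).
#' @param reporter_len reporter ORF length.
#' @return list of class `Backbone` with `sequence` and a `features` table
#'   (0-based half-open `start`, `end`).
#' @export
make_backbone <- function(seed = 1L, promoter_len = 134L, reporter_len = 720L) {
  set.seed(derive_seed(seed, "backbone"))
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  scrub <- function(s) {
    # remove chance restriction sites from random filler
    repeat {
      hits <- check_internal_sites(s)
      if (!nrow(hits)) return(s)
      p <- hits$position[1] + 3L
      substr(s, p + 1, p + 1) <- c(A = "C", C = "A", G = "T", T = "G", N = "A")[
        substr(s, p + 1, p + 1)]
    }
  }
  seg <- list(
    stuffer = scrub(rand_dna(400L)),
    ecoRI = ECORI_SITE,
    spacer = scrub(rand_dna(20L)),
    salI = SALI_SITE,
    promoter = scrub(rand_dna(promoter_len)),
    reporter = paste0("ATG", scrub(rand_dna(reporter_len - 6L)), "TAA"),
    polyA = scrub(rand_dna(49L)),
    tail = scrub(rand_dna(200L)))
  sequence <- paste(unlist(seg), collapse = "")
  ends <- cumsum(vapply(seg, nchar, 0L))
  starts <- ends - vapply(seg, nchar, 0L)
  # segment junctions can recreate a site by chance; scrub all but the polylinker
  repeat {
    hits <- check_internal_sites(sequence)
    stray <- hits$position[!hits$position %in% c(starts[["ecoRI"]], starts[["salI"]])]
    if (!length(stray)) break
    p <- stray[1] + 3L
    substr(sequence, p + 1, p + 1) <- c(A = "C", C = "A", G = "T", T = "G", N = "A")[
      substr(sequence, p + 1, p + 1)]
  }
  feats <- data.frame(name = c("polylinker_EcoRI", "polylinker_SalI",
                               "minimal_promoter_synthetic", "reporter", "polyA"),
                      start = starts[c("ecoRI", "salI", "promoter", "reporter", "polyA")],
                      end = ends[c("ecoRI", "salI", "promoter", "reporter", "polyA")],
                      strand = "+", stringsAsFactors = FALSE)
  rownames(feats) <- NULL
  # the global scrub may have touched the polylinker flanks; re-assert sites
  stopifnot(substr(sequence, feats$start[1] + 1, feats$end[1]) == ECORI_SITE,
            substr(sequence, feats$start[2] + 1, feats$end[2]) == SALI_SITE)
  structure(list(sequence = sequence, features = feats), class = "Backbone")
}

#' Sticky-end assembly of an EDGE construct
#'
#' Digests the amplicon and the backbone with EcoRI and SalI (top-strand cuts
#' `G^AATTC`, `G^TCGAC`) and ligates the insert into the polylinker. Both
#' flanking sites reconstitute, so re-digestion releases an insert identical
#' to the amplicon interior. The amplicon must carry exactly one EcoRI and one
#' SalI site (its designed flanks); internal sites abort the assembly.
#'
#' @param amplicon an [in_silico_pcr()] product.
#' @param backbone a [make_backbone()] object (or compatible list).
#' @return list of class `Construct` with `sequence` and `features`
#'   (backbone features shifted, plus the `enhancer_insert`).
#' @export
assemble_construct <- function(amplicon, backbone) {
  amplicon <- check_dna(amplicon)
  bb_seq <- check_dna(backbone$sequence)
  bb_sites <- check_internal_sites(bb_seq)
  e_b <- bb_sites$position[bb_sites$site == ECORI_SITE]
  s_b <- bb_sites$position[bb_sites$site == SALI_SITE]
  if (length(e_b) != 1 || length(s_b) != 1)
    stop("backbone polylinker must contain exactly one EcoRI and one SalI site")
  if (e_b >= s_b) stop("backbone EcoRI site must lie upstream of the SalI site")

  amp_sites <- check_internal_sites(amplicon)
  e_a <- amp_sites$position[amp_sites$site == ECORI_SITE]
  s_a <- amp_sites$position[amp_sites$site == SALI_SITE]
  if (length(e_a) != 1 || length(s_a) != 1 || e_a >= s_a)
    stop("amplicon must carry exactly one EcoRI and one SalI site in order; ",
         "screen inserts with check_internal_sites() before cloning")

  # 0-based top-strand cut points
  cut_e_b <- e_b + CUT_OFFSET; cut_s_b <- s_b + CUT_OFFSET
  cut_e_a <- e_a + CUT_OFFSET; cut_s_a <- s_a + CUT_OFFSET
  insert <- substr(amplicon, cut_e_a + 1, cut_s_a)       # AATTC ... G
  upstream <- substr(bb_seq, 1, cut_e_b)                 # ... G
  downstream <- substr(bb_seq, cut_s_b + 1, nchar(bb_seq)) # TCGAC ...
  sequence <- paste0(upstream, insert, downstream)

  delta <- nchar(insert) - (cut_s_b - cut_e_b)
  feats <- backbone$features
  after <- feats$start >= cut_s_b
  feats$start[after] <- feats$start[after] + delta
  feats$end[after] <- feats$end[after] + delta
  # SalI feature sits across the downstream cut; recompute both site features
  feats$start[feats$name == "polylinker_EcoRI"] <- e_b
  feats$end[feats$name == "polylinker_EcoRI"] <- e_b + 6L
  new_s <- cut_e_b + nchar(insert) - 1L
  feats$start[feats$name == "polylinker_SalI"] <- new_s
  feats$end[feats$name == "polylinker_SalI"] <- new_s + 6L
  enh_start <- cut_e_b + 5L            # insert = AATTC | enhancer | G
  enh_end <- cut_e_b + nchar(insert) - 1L
  feats <- rbind(feats,
                 data.frame(name = "enhancer_insert", start = enh_start,
                            end = enh_end, strand = "+", stringsAsFactors = FALSE))
  feats <- feats[order(feats$start), , drop = FALSE]
  rownames(feats) <- NULL
  out <- structure(list(sequence = sequence, features = feats), class = "Construct")
  # both sites must have reconstituted
  stopifnot(identical(digest_construct(out), insert))
  out
}

#' Re-digest a construct
#'
#' Cuts the assembled construct at its unique EcoRI and SalI sites and returns
#' the released insert (the amplicon interior between the two cut points).
#'
#' @param construct an [assemble_construct()] result.
#' @return insert sequence between the top-strand cut points.
#' @export
digest_construct <- function(construct) {
  seq <- construct$sequence
  sites <- check_internal_sites(seq)
  e <- sites$position[sites$site == ECORI_SITE]
  s <- sites$position[sites$site == SALI_SITE]
  if (length(e) != 1 || length(s) != 1 || e >= s)
    stop("construct must contain exactly one EcoRI site upstream of one SalI site")
  substr(seq, e + CUT_OFFSET + 1, s + CUT_OFFSET)
}

#' Recover the enhancer from an assembled construct
#'
#' Strips the sticky-end remnants (`AATTC` prefix, `G` suffix) from the
#' re-digested insert, inverting the full design -> PCR -> digest -> ligate
#' chain for site-free enhancers.
#'
#' @param construct an [assemble_construct()] result.
#' @return the enhancer sequence.
#' @export
extract_insert_enhancer <- function(construct) {
  insert <- digest_construct(construct)
  stopifnot(startsWith(insert, "AATTC"), endsWith(insert, "G"))
  substr(insert, 6, nchar(insert) - 1)
}
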