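# Disintegrin candidate detection: an integrin-binding triad (RGD, KGD,
# KTS, RTS or RED) is a credible disintegrin site when it sits on a
# hairpin protruding from the protein body, stapled by a disulfide
# between cysteines flanking the triad. "Protruding" is operationalised
# as a z-score of the triad centroid's distance from the whole-chain
# C-alpha centroid against the per-residue centroid-distance
# distribution, which is invariant under rigid motion and needs no
# solvent-accessibility machinery.

TRIADS <- c("RGD", "KGD", "KTS", "RTS", "RED")

locate_triad <- function(matched, start) {
  if (nchar(matched) == 3L && matched %in% TRIADS) {
    return(list(triad = matched, start = start))
  }
  for (tr in TRIADS) {
    p <- regexpr(tr, matched, fixed = TRUE)
    if (p > 0L) return(list(triad = tr, start = start + p - 1L))
  }
  NULL
}

#' Find disintegrin candidates in one record
#'
#' For every triad motif hit: the nearest cysteine at most `window`
#' residues before the triad and the nearest at most `window` residues
#' after it form the flank pair (nearest-per-side minimises the combined
#' distance); `bridge_bonded` is true iff that pair is disulfide-bonded
#' in the topology; `protrusion_z` measures how far the triad sticks out
#' of the body; `hairpin` requires both the bridge and `protrusion_z >=
#' protrusion_threshold`.
#'
#' @param record [seq_record()] with a sequence.
#' @param model `pdb_model` for the same protein (residue numbering equal
#'   to sequence position), or `NULL` for sequence-only screening.
#' @param topology [detect_bonds()] result for `model` (computed when
#'   missing).
#' @param motif_hits hits from the disintegrin block patterns for this
#'   record.
#' @param window max residues between triad and flanking cysteine.
#' @param protrusion_threshold z-score floor for "protruding".
#' @return data.frame (one row per triad hit): record_id, triad,
#'   triad_start, flank_before, flank_after, bridge_bonded, protrusion_z,
#'   hairpin, rank_score.
#' @export
find_candidates <- function(record, model = NULL, topology = NULL,
                            motif_hits = NULL, window = 10L,
                            protrusion_threshold = 1.5) {
  empty <- data.frame(record_id = character(), triad = character(),
                      triad_start = integer(), flank_before = integer(),
                      flank_after = integer(), bridge_bonded = logical(),
                      protrusion_z = numeric(), hairpin = logical(),
                      rank_score = numeric(), stringsAsFactors = FALSE)
  if (is.null(motif_hits) || nrow(motif_hits) == 0L) return(empty)
  mh <- motif_hits[motif_hits$record_id == record$record_id, ,
                   drop = FALSE]
  if (nrow(mh) == 0L) return(empty)
  seqs <- record$sequence
  if (is.na(seqs)) stop("record '", record$record_id, "' has no sequence",
                        call. = FALSE)
  n <- nchar(seqs)
  cys_pos <- which(strsplit(seqs, "")[[1]] == "C")

  have_model <- !is.null(model)
  ca <- NULL
  dists <- NULL
  if (have_model) {
    chain <- model_chains(model)[[1]]
    ca <- model_ca(model, chain)
    if (nrow(ca) != n) {
      stop("record '", record$record_id, "': model has ", nrow(ca),
           " CA residues but sequence has ", n, call. = FALSE)
    }
    if (is.null(topology)) topology <- detect_bonds(model)
    centroid <- colMeans(ca)
    dists <- sqrt(rowSums(sweep(ca, 2L, centroid)^2))
  }

  rows <- list()
  for (i in seq_len(nrow(mh))) {
    tri <- locate_triad(mh$matched[[i]], mh$start[[i]])
    if (is.null(tri)) next
    ts <- tri$start
    te <- ts + 2L
    before <- cys_pos[cys_pos < ts & ts - cys_pos <= window]
    after <- cys_pos[cys_pos > te & cys_pos - te <= window]
    fb <- if (length(before)) max(before) else NA_integer_
    fa <- if (length(after)) min(after) else NA_integer_
    bonded <- FALSE
    if (!is.na(fb) && !is.na(fa) && have_model) {
      b <- topology$bonds
      bonded <- any((b$res_a == fb & b$res_b == fa) |
                      (b$res_a == fa & b$res_b == fb))
    } else if (!is.na(fb) && !is.na(fa) && !have_model) {
      bonded <- NA
    }
    pz <- NA_real_
    if (have_model) {
      tri_centroid <- colMeans(ca[ts:te, , drop = FALSE])
      D <- sqrt(sum((tri_centroid - colMeans(ca))^2))
      pz <- (D - mean(dists)) / sd(dists)
    }
    hairpin <- isTRUE(bonded) && !is.na(pz) &&
      pz >= protrusion_threshold
    rows[[length(rows) + 1L]] <- data.frame(
      record_id = record$record_id, triad = tri$triad, triad_start = ts,
      flank_before = fb, flank_after = fa,
      bridge_bonded = if (is.na(bonded)) FALSE else bonded,
      protrusion_z = pz, hairpin = hairpin,
      rank_score = if (hairpin) pz else 0,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen a batch of records for disintegrin candidates
#'
#' Records without a model are screened sequence-only (motif evidence
#' only, `model_available = FALSE`, never hairpin-confirmed).
#'
#' @param records list of [seq_record()].
#' @param models named list of `pdb_model` keyed by record id (entries
#'   may be missing).
#' @param library motif library; defaults to the disintegrin triad
#'   blocks.
#' @param window,protrusion_threshold see [find_candidates()].
#' @return list: `candidates` (data.frame sorted by rank_score
#'   descending, with `model_available`), `summary` (counts: records
#'   screened, motif-only candidates, hairpin-confirmed candidates).
#' @export
batch_screen <- function(records, models = list(),
                         library = disintegrin_blocks(),
                         window = 10L, protrusion_threshold = 1.5) {
  scan <- scan_database(library, records)
  rows <- list()
  for (rec in records) {
    mdl <- models[[rec$record_id]]
    cand <- find_candidates(rec, model = mdl, motif_hits = scan$hits,
                            window = window,
                            protrusion_threshold = protrusion_threshold)
    if (nrow(cand)) {
      cand$model_available <- !is.null(mdl)
      rows[[length(rows) + 1L]] <- cand
    }
  }
  candidates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(), triad = character(),
               triad_start = integer(), flank_before = integer(),
               flank_after = integer(), bridge_bonded = logical(),
               protrusion_z = numeric(), hairpin = logical(),
               rank_score = numeric(), model_available = logical(),
               stringsAsFactors = FALSE)
  candidates <- candidates[order(-candidates$rank_score,
                                 candidates$record_id), , drop = FALSE]
  rownames(candidates) <- NULL
  list(candidates = candidates,
       summary = c(records = length(records),
                   motif_flagged = sum(scan$flagged),
                   motif_only = sum(!candidates$hairpin),
                   hairpin_confirmed = sum(candidates$hairpin)))
}
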