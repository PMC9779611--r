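# Interpretation of structural-search (Dali-style) hit tables: Z-score
# bands, best-hit selection, family reassignment rules and the
# motif-rename ledger. Z bands follow the Dali manual: above 20 the two
# structures are homologous, 8-20 probably homologous, 2-8 a gray area,
# below 2 not significant. The prose shares interval endpoints, so bands
# are implemented half-open: [20,Inf), [8,20), [2,8), (-Inf,2).

Z_BANDS <- c(homologous = 20, probably_homologous = 8, gray = 2)

#' Z-score band of a structural-search hit
#'
#' @param z finite numeric Z score (vectorised).
#' @return factor-like character: `"homologous"` (z >= 20),
#'   `"probably_homologous"` (8 <= z < 20), `"gray"` (2 <= z < 8) or
#'   `"not_significant"` (z < 2).
#' @export
zband <- function(z) {
  if (any(!is.finite(z))) stop("non-finite Z score", call. = FALSE)
  out <- rep("not_significant", length(z))
  out[z >= Z_BANDS[["gray"]]] <- "gray"
  out[z >= Z_BANDS[["probably_homologous"]]] <- "probably_homologous"
  out[z >= Z_BANDS[["homologous"]]] <- "homologous"
  out
}

band_rank <- function(band) {
  match(band, c("not_significant", "gray", "probably_homologous",
                "homologous"))
}

#' Read a Dali-style hit table
#'
#' Two dialects: a strict TSV with header columns `query_id`,
#' `target_pdb`, `z`, `rmsd`, `lali`, `pct_id`, `description`; or a
#' lenient whitespace-separated layout with the same first six fields and
#' the remainder of the line as description.
#'
#' @param path hit table file.
#' @return data.frame of hits.
#' @export
read_dali_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0L) {
    return(data.frame(query_id = character(), target_pdb = character(),
                      z = numeric(), rmsd = numeric(), lali = integer(),
                      pct_id = numeric(), description = character(),
                      stringsAsFactors = FALSE))
  }
  if (grepl("\t", lines[[1]])) {
    df <- read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                     header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE, quote = "")
    need <- c("query_id", "target_pdb", "z", "rmsd", "lali", "pct_id",
              "description")
    missing <- setdiff(need, names(df))
    if (length(missing)) {
      stop("hit table lacks column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    df <- df[, need]
  } else {
    rows <- lapply(lines, function(ln) {
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(toks) < 6L) stop("malformed hit line: '", ln, "'",
                                  call. = FALSE)
      data.frame(query_id = toks[[1]], target_pdb = toks[[2]],
                 z = toks[[3]], rmsd = toks[[4]], lali = toks[[5]],
                 pct_id = toks[[6]],
                 description = paste(toks[-(1:6)], collapse = " "),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  }
  df$z <- as.numeric(df$z)
  df$rmsd <- as.numeric(df$rmsd)
  df$lali <- as.integer(df$lali)
  df$pct_id <- as.numeric(df$pct_id)
  if (any(!is.finite(df$z))) stop("non-finite Z score in hit table",
                                  call. = FALSE)
  if (any(df$lali < 0L, na.rm = TRUE)) stop("negative lali",
                                            call. = FALSE)
  df
}

#' Default target-categorization map
#'
#' Categorisation of matched PDB entries is data, not code: each category
#' owns a set of PDB id+chain accessions (checked first) and lowercase
#' description keywords. The bacterial pore-forming set carries the seven
#' toxin structures used for the cytotoxin call (2d42-A, 4rhz-A, 3zjx-A,
#' 2ztb-B, 7ml9-A, 6lh8-A, 1w3a-A).
#'
#' @return named list: category -> list(pdb_ids, keywords).
#' @export
target_category_map <- function() {
  list(
    bacterial_pore_toxin = list(
      pdb_ids = c("2d42-A", "4rhz-A", "3zjx-A", "2ztb-B", "7ml9-A",
                  "6lh8-A", "1w3a-A"),
      keywords = c("epsilon-toxin", "aerolysin", "crystal protein",
                   "hemolytic lectin", "pore-forming")),
    metalloprotease = list(
      pdb_ids = character(),
      keywords = c("metalloprotease", "metalloproteinase", "adamalysin",
                   "reprolysin", "leucurolysin", "adam")),
    lipocalin = list(
      pdb_ids = character(),
      keywords = c("lipocalin", "histamine-binding", "histamine binding",
                   "jacalin")),
    ml_domain = list(
      pdb_ids = character(),
      keywords = c("niemann-pick", "npc2", "ml domain", "der p 2",
                   "der f 2")),
    der_f7_jhbp = list(
      pdb_ids = character(),
      keywords = c("der f 7", "juvenile hormone")),
    sulfotransferase = list(pdb_ids = character(),
                            keywords = "sulfotransferase"),
    evasin = list(pdb_ids = character(), keywords = "evasin"),
    kunitz = list(pdb_ids = character(),
                  keywords = c("kunitz", "bpti", "trypsin inhibitor")))
}

#' Categorise a structural-search target
#'
#' @param hit one row of a hit table (list or 1-row data.frame).
#' @param category_map see [target_category_map()].
#' @return category name, `"other"` when nothing matches. PDB-id matches
#'   take precedence over keyword matches; categories are tried in map
#'   order.
#' @export
target_category <- function(hit, category_map = target_category_map()) {
  for (cat in names(category_map)) {
    if (hit$target_pdb %in% category_map[[cat]]$pdb_ids) return(cat)
  }
  desc <- tolower(hit$description %||% "")
  for (cat in names(category_map)) {
    kws <- category_map[[cat]]$keywords
    if (length(kws) && any(vapply(kws, grepl, TRUE, x = desc,
                                  fixed = TRUE))) {
      return(cat)
    }
  }
  "other"
}

#' Best hit for one query
#'
#' Maximal Z; ties broken by lower RMSD, then lexicographic target id.
#'
#' @param hits data.frame of hits for a single query (>= 1 row).
#' @return the selected row as a one-row data.frame.
#' @export
best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) stop("no hits", call. = FALSE)
  o <- order(-hits$z, hits$rmsd, hits$target_pdb)
  hits[o[[1]], , drop = FALSE]
}

#' Default per-rule Z floors for the reassignment rules
#' @return named numeric vector, editable and passable to [classify()].
#' @export
rule_z_floors <- function() {
  c(metalloproteoid = Z_BANDS[["probably_homologous"]],  # R1/R2: band >= probably
    cytotoxin = 10,       # printed range 10-16
    der_f7 = 10,          # "Z scores above 10"
    niemann_pick = 12,    # "Z values above 12"
    lipocalin = Z_BANDS[["probably_homologous"]],
    sulfotransferase = Z_BANDS[["gray"]])
}

#' Classify one query by its structural hits and motif evidence
#'
#' Applies the family-reassignment rules in fixed priority order; the
#' first matching rule fires. The metalloproteoid/metalloprotease
#' decision (R1/R2) hinges solely on the presence of the catalytic
#' zinc-binding motif in the query sequence: a metalloprotease-fold match
#' without the motif is a metalloproteoid (a non-catalytic
#' metalloprotease-like protein). R7 is the fall-through: queries with no
#' hits, a non-significant best hit, or no applicable rule are reported
#' as having no significant structural match.
#'
#' @param record a [seq_record()] (supplies query id and old family).
#' @param hits hit data.frame for this query (may be empty/NULL).
#' @param motif_hits motif hit data.frame (from [scan_database()]); only
#'   rows for this record are consulted.
#' @param z_floors per-rule Z floors, see [rule_z_floors()].
#' @param category_map see [target_category_map()].
#' @return object of class `family_assignment`: query_id, old_family,
#'   new_group, new_subgroup, rule_id, evidence.
#' @export
classify <- function(record, hits, motif_hits = NULL,
                     z_floors = rule_z_floors(),
                     category_map = target_category_map()) {
  qid <- record$record_id
  old <- record$family
  sub <- if (nzchar(old)) old else "unspecified"
  mh <- if (is.null(motif_hits) || nrow(motif_hits) == 0L) {
    character()
  } else {
    motif_hits$pattern_id[motif_hits$record_id == qid]
  }
  zinc <- "ZINC_BINDING" %in% mh
  mk <- function(group, rule, bh = NULL) {
    structure(list(
      query_id = qid, old_family = old, new_group = group,
      new_subgroup = sub, rule_id = rule,
      evidence = list(
        best_target = if (is.null(bh)) NA_character_ else bh$target_pdb,
        z = if (is.null(bh)) NA_real_ else bh$z,
        band = if (is.null(bh)) NA_character_ else zband(bh$z),
        zinc_motif = zinc, motif_hits = mh)),
      class = "family_assignment")
  }
  if (is.null(hits) || nrow(hits) == 0L) {
    return(mk("no significant structural match", "R7"))
  }
  bh <- best_hit(hits)
  band <- zband(bh$z)
  if (band == "not_significant") {
    return(mk("no significant structural match", "R7", bh))
  }
  cat <- target_category(bh, category_map)
  if (cat == "metalloprotease" &&
      bh$z >= z_floors[["metalloproteoid"]]) {
    if (!zinc) return(mk("Metalloproteoid", "R1", bh))
    return(mk("Metalloprotease", "R2", bh))
  }
  if (cat == "bacterial_pore_toxin" && bh$z >= z_floors[["cytotoxin"]]) {
    return(mk("Cytotoxin", "R3", bh))
  }
  if (cat == "der_f7_jhbp" && bh$z > z_floors[["der_f7"]]) {
    return(mk("Der f 7 allergen/JHBP", "R4", bh))
  }
  if (cat == "ml_domain" && bh$z > z_floors[["niemann_pick"]]) {
    return(mk("Niemann-Pick", "R5", bh))
  }
  if (cat == "lipocalin" &&
      band_rank(band) >= band_rank("probably_homologous")) {
    return(mk("Lipocalin", "R6", bh))
  }
  if (cat == "sulfotransferase" &&
      bh$z >= z_floors[["sulfotransferase"]]) {
    return(mk("Sulfotransferase", "R6s", bh))
  }
  mk("no significant structural match", "R7", bh)
}

#' @export
print.family_assignment <- function(x, ...) {
  cat(sprintf("<family_assignment %s> %s -> %s [%s]\n", x$query_id,
              if (nzchar(x$old_family)) x$old_family else "(none)",
              x$new_group, x$rule_id))
  invisible(x)
}

#' Classify a batch of queries
#'
#' @param records list of [seq_record()].
#' @param hits full hit table (all queries).
#' @param motif_hits motif hit table.
#' @param ... forwarded to [classify()].
#' @return data.frame: query_id, old_family, new_group, new_subgroup,
#'   rule_id, best_target, z, band — one row per record.
#' @export
classify_batch <- function(records, hits, motif_hits = NULL, ...) {
  rows <- lapply(records, function(rec) {
    h <- hits[hits$query_id == rec$record_id, , drop = FALSE]
    a <- classify(rec, h, motif_hits, ...)
    data.frame(query_id = a$query_id, old_family = a$old_family,
               new_group = a$new_group, new_subgroup = a$new_subgroup,
               rule_id = a$rule_id,
               best_target = a$evidence$best_target, z = a$evidence$z,
               band = a$evidence$band, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# cluster-model ids whose PSSM was found to pull in zinc-motif-free
# metalloprotease-fold sequences, plus individually renamed models
MOTIF_RENAMES <- c(
  "40-800" = "Kunitz",
  "40-584" = "acid tail",
  "35-53" = "Lipocalin",
  "Rapp-25-325" = "cystatin",
  "25-159" = "Cytochrome_B2",
  "30-49" = "Metalloproteoid", "30-561" = "Metalloproteoid",
  "30-93" = "Metalloproteoid", "35-121" = "Metalloproteoid",
  "35-167" = "Metalloproteoid", "35-414" = "Metalloproteoid",
  "35-415" = "Metalloproteoid", "35-768" = "Metalloproteoid",
  "35-77" = "Metalloproteoid", "50-341" = "Metalloproteoid")

#' Look up the renamed family label of a cluster-model id
#'
#' Static rename ledger for PSSM model ids whose family assignment was
#' revised after the structural reanalysis. Unknown ids map to themselves
#' with a message.
#'
#' @param motif_model_id e.g. `"40-800"`.
#' @return new family label (or the id itself when not in the ledger).
#' @export
rename_motif <- function(motif_model_id) {
  stopifnot(is.character(motif_model_id), length(motif_model_id) == 1L)
  if (motif_model_id %in% names(MOTIF_RENAMES)) {
    return(unname(MOTIF_RENAMES[[motif_model_id]]))
  }
  message("rename_motif: id '", motif_model_id,
          "' not in rename ledger; returned unchanged")
  motif_model_id
}
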