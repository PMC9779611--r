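# PROSITE-syntax motif compilation and scanning (ps_scan semantics).
# A pattern is a "-"-separated list of elements: a residue letter, "x"
# (wildcard), "[..]" (allowed set), "{..}" (excluded set), each with an
# optional "(n)" or "(n,m)" repeat; "<"/">" anchor to the termini; a
# trailing "." is ignored. Matching reports every start position; within a
# start, variable repeats are resolved greedily so the longest match at
# that start is the one reported.
#
# Masked residues: "x" matches any residue including "X"; a specific
# letter or an allowed set never matches "X" (unless the set lists it);
# an exclusion set matches "X" unless "X" is excluded. This conservative
# rule prevents spurious motif calls on masked positions.

#' Compile a PROSITE-syntax pattern
#'
#' @param prosite_text pattern, e.g. `"H-E-x(2)-H-x(2)-G-x(2)-H"`.
#' @param pattern_id identifier carried into hits.
#' @return object of class `motif_pattern` with the compiled element list.
#' @export
compile_pattern <- function(prosite_text, pattern_id = prosite_text) {
  stopifnot(is.character(prosite_text), length(prosite_text) == 1L)
  txt <- trimws(prosite_text)
  txt <- sub("\\.$", "", txt)
  anchor_n <- grepl("^<", txt)
  anchor_c <- grepl(">$", txt)
  txt <- sub("^<", "", txt)
  txt <- sub(">$", "", txt)
  if (!nzchar(txt)) stop("empty pattern", call. = FALSE)
  toks <- strsplit(txt, "-", fixed = TRUE)[[1]]
  elements <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    tok <- toks[[i]]
    if (!nzchar(tok)) {
      stop("pattern '", prosite_text, "': empty element at position ", i,
           call. = FALSE)
    }
    min_rep <- 1L
    max_rep <- 1L
    rep_match <- regmatches(tok, regexpr("\\([^)]*\\)$", tok))
    if (length(rep_match) == 1L && nzchar(rep_match)) {
      body <- substr(rep_match, 2L, nchar(rep_match) - 1L)
      if (grepl("^[0-9]+$", body)) {
        min_rep <- max_rep <- as.integer(body)
      } else if (grepl("^[0-9]+,[0-9]+$", body)) {
        nm <- as.integer(strsplit(body, ",")[[1]])
        min_rep <- nm[[1]]
        max_rep <- nm[[2]]
      } else {
        stop("pattern '", prosite_text, "': bad repeat '", rep_match,
             "' at element ", i, call. = FALSE)
      }
      tok <- sub("\\([^)]*\\)$", "", tok)
    } else if (grepl("[()]", tok)) {
      stop("pattern '", prosite_text, "': unbalanced parentheses at ",
           "element ", i, call. = FALSE)
    }
    if (max_rep < 1L || min_rep < 0L || min_rep > max_rep) {
      stop("pattern '", prosite_text, "': invalid repeat range at ",
           "element ", i, call. = FALSE)
    }
    el <- if (tok %in% c("x", "X")) {
      list(type = "any", residues = "")
    } else if (grepl("^\\[[A-Za-z]+\\]$", tok)) {
      list(type = "set",
           residues = toupper(substr(tok, 2L, nchar(tok) - 1L)))
    } else if (grepl("^\\{[A-Za-z]+\\}$", tok)) {
      list(type = "exclude",
           residues = toupper(substr(tok, 2L, nchar(tok) - 1L)))
    } else if (grepl("^[A-Za-z]$", tok)) {
      list(type = "res", residues = toupper(tok))
    } else {
      stop("pattern '", prosite_text, "': malformed element '", tok,
           "' at position ", i, call. = FALSE)
    }
    if (el$type != "any") {
      bad <- setdiff(strsplit(el$residues, "")[[1]], AA_ALPHABET)
      if (length(bad)) {
        stop("pattern '", prosite_text, "': unknown residue letter '",
             bad[[1]], "' at element ", i, call. = FALSE)
      }
    }
    el$min <- min_rep
    el$max <- max_rep
    elements[[i]] <- el
  }
  structure(list(pattern_id = pattern_id, prosite_text = prosite_text,
                 elements = elements, anchor_n = anchor_n,
                 anchor_c = anchor_c),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern %s> %s (%d elements)\n", x$pattern_id,
              x$prosite_text, length(x$elements)))
  invisible(x)
}

element_matches <- function(el, ch) {
  switch(el$type,
         any = TRUE,
         res = ch == el$residues,
         set = grepl(ch, el$residues, fixed = TRUE),
         exclude = !grepl(ch, el$residues, fixed = TRUE))
}

# longest feasible match of elements[k..] starting at position pos
# (1-based); returns end position (>= pos - 1 for empty tail) or -1L.
match_from <- function(chars, elements, k, pos, anchor_c) {
  if (k > length(elements)) {
    if (anchor_c && pos != length(chars) + 1L) return(-1L)
    return(pos - 1L)
  }
  el <- elements[[k]]
  # count feasible consecutive matches of this element
  feasible <- 0L
  while (feasible < el$max && pos + feasible <= length(chars) &&
         element_matches(el, chars[[pos + feasible]])) {
    feasible <- feasible + 1L
  }
  if (feasible < el$min) return(-1L)
  for (take in seq(feasible, el$min)) {   # greedy: longest first
    res <- match_from(chars, elements, k + 1L, pos + take, anchor_c)
    if (res >= 0L) return(res)
  }
  -1L
}

#' Scan one sequence with a compiled pattern
#'
#' Every match start position is reported (overlaps allowed); at each
#' start the greedy-longest match is the single hit. Coordinates are
#' 1-based inclusive.
#'
#' @param pattern a [compile_pattern()] result.
#' @param record a [seq_record()] (or a plain sequence string, in which
#'   case `record_id` labels the hits).
#' @param record_id id used when `record` is a bare string.
#' @return data.frame with columns `pattern_id`, `record_id`, `start`,
#'   `end`, `matched`.
#' @export
scan_sequence <- function(pattern, record, record_id = "seq") {
  stopifnot(inherits(pattern, "motif_pattern"))
  if (inherits(record, "seq_record")) {
    seqs <- record$sequence
    record_id <- record$record_id
  } else {
    seqs <- toupper(record)
  }
  if (is.na(seqs)) stop("record '", record_id, "' has no sequence",
                        call. = FALSE)
  chars <- strsplit(seqs, "")[[1]]
  starts <- if (pattern$anchor_n) 1L else seq_along(chars)
  hits <- list()
  for (s in starts) {
    e <- match_from(chars, pattern$elements, 1L, s, pattern$anchor_c)
    if (e >= s) {
      hits[[length(hits) + 1L]] <- data.frame(
        pattern_id = pattern$pattern_id, record_id = record_id,
        start = s, end = e, matched = substr(seqs, s, e),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(pattern_id = character(), record_id = character(),
                      start = integer(), end = integer(),
                      matched = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Built-in motif library
#'
#' Ships the motifs used throughout the annotation rules:
#' \describe{
#'   \item{ZINC_BINDING}{`H-E-x(2)-H-x(2)-G-x(2)-H`, the catalytic
#'     zinc-binding histidine motif of metalloproteases. Its absence in a
#'     protein whose fold matches metalloproteases defines the
#'     metalloproteoid group.}
#'   \item{P450_HEME}{`F-x-x-G-x-[HR]-x-C-x-G`, the cytochrome P450
#'     heme-pocket motif whose conserved cysteine ligates the heme iron.}
#'   \item{P450_CATALYTIC}{`[AG]-G-x-[ED]-T`, the conserved
#'     acid/threonine pair of the P450 active site.}
#' }
#' plus, when `include_disintegrin = TRUE`, the disintegrin triad blocks
#' from [disintegrin_blocks()].
#'
#' @param include_disintegrin include the disintegrin triad patterns.
#' @param flanked pass-through to [disintegrin_blocks()].
#' @return named list of `motif_pattern`, class `motif_library`.
#' @export
motif_library <- function(include_disintegrin = TRUE, flanked = FALSE) {
  pats <- list(
    ZINC_BINDING = compile_pattern("H-E-x(2)-H-x(2)-G-x(2)-H",
                                   "ZINC_BINDING"),
    P450_HEME = compile_pattern("F-x-x-G-x-[HR]-x-C-x-G", "P450_HEME"),
    P450_CATALYTIC = compile_pattern("[AG]-G-x-[ED]-T", "P450_CATALYTIC"))
  if (include_disintegrin) {
    pats <- c(pats, disintegrin_blocks(flanked = flanked))
  }
  structure(pats, class = "motif_library")
}

#' Disintegrin triad motif blocks
#'
#' The integrin-binding triads seen in salivary and venom disintegrins:
#' RGD, KGD, KTS, RTS and RED. With `flanked = TRUE` each triad is
#' additionally required to have a cysteine within `flank` residues on
#' each side (the pair that can staple the hairpin), i.e.
#' `C-x(0,flank-1)-R-G-D-x(0,flank-1)-C`. The default is the bare triads;
#' hairpin geometry is checked downstream by the disintegrin finder.
#'
#' @param flanked require cysteine context.
#' @param flank window size in residues.
#' @return named list of `motif_pattern`.
#' @export
disintegrin_blocks <- function(flanked = FALSE, flank = 10L) {
  triads <- c(RGD = "R-G-D", KGD = "K-G-D", KTS = "K-T-S",
              RTS = "R-T-S", RED = "R-E-D")
  out <- list()
  for (nm in names(triads)) {
    pat <- triads[[nm]]
    if (flanked) {
      pat <- sprintf("C-x(0,%d)-%s-x(0,%d)-C", flank - 1L, pat,
                     flank - 1L)
    }
    id <- paste0("DISINTEGRIN_", nm, if (flanked) "_CFLANK" else "")
    out[[id]] <- compile_pattern(pat, id)
  }
  out
}

#' Read a PROSITE-format motif file (ID/PA line subset)
#'
#' Accepts entries of the form
#' \preformatted{ID  NAME; PATTERN.
#' PA  <pattern>.
#' //}
#' Multi-line `PA` records are concatenated.
#'
#' @param path motif file.
#' @return named list of `motif_pattern`, class `motif_library`.
#' @export
read_prosite_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  pats <- list()
  id <- NULL
  pa <- character()
  flush_entry <- function() {
    if (!is.null(id) && length(pa)) {
      pats[[id]] <<- compile_pattern(paste(pa, collapse = ""), id)
    }
    id <<- NULL
    pa <<- character()
  }
  for (ln in lines) {
    if (grepl("^ID\\s", ln)) {
      flush_entry()
      id <- sub(";.*$", "", sub("^ID\\s+", "", ln))
      id <- trimws(id)
    } else if (grepl("^PA\\s", ln)) {
      pa <- c(pa, trimws(sub("^PA\\s+", "", ln)))
    } else if (grepl("^//", ln)) {
      flush_entry()
    }
  }
  flush_entry()
  if (length(pats) == 0L) stop("no patterns found in ", path,
                               call. = FALSE)
  structure(pats, class = "motif_library")
}

#' Scan a set of records with a motif library
#'
#' @param library `motif_library` (or plain list of patterns).
#' @param records list of [seq_record()].
#' @return list with `hits` (data.frame sorted by record_id then start)
#'   and `flagged` (named logical: any hit from any pattern).
#' @export
scan_database <- function(library, records) {
  ids <- vapply(records, `[[`, "", "record_id")
  hit_list <- list()
  for (rec in records) {
    if (is.na(rec$sequence)) next
    for (pat in library) {
      h <- scan_sequence(pat, rec)
      if (nrow(h)) hit_list[[length(hit_list) + 1L]] <- h
    }
  }
  hits <- if (length(hit_list)) do.call(rbind, hit_list) else
    data.frame(pattern_id = character(), record_id = character(),
               start = integer(), end = integer(), matched = character(),
               stringsAsFactors = FALSE)
  hits <- hits[order(hits$record_id, hits$start, hits$pattern_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  flagged <- setNames(ids %in% hits$record_id, ids)
  list(hits = hits, flagged = flagged)
}

#' Write motif hits as TSV
#' @param hits hit data.frame from [scan_database()] or [scan_sequence()].
#' @param path output path.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
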