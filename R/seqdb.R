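# Sequence database: FASTA and annotation-table I/O, family tabulation,
# cluster-id scheme "<identity>-<index>" where identity is the percent
# identity threshold of the upstream clustering (25, 30, ..., 95).

CLUSTER_THRESHOLDS <- seq(25L, 95L, by = 5L)

#' Construct a sequence record
#'
#' One entry of the secreted-salivary-protein database. `sequence` may be
#' `NA` for annotation-only records (rows read from a spreadsheet that
#' carries no sequence column); when present it must be non-empty and drawn
#' from the 20 amino-acid letters plus `X`.
#'
#' @param record_id accession string, unique within a database.
#' @param sequence amino-acid string or `NA`.
#' @param description free-text description.
#' @param family,subgroup family/group labels, `""` when unannotated.
#' @param cluster_ids list of cluster ids (see [parse_cluster_id()]).
#' @param disintegrin_flag logical, mirrors the annotation spreadsheet's
#'   disintegrin-motif column.
#' @param species free text.
#' @return an object of class `seq_record`.
#' @export
seq_record <- function(record_id, sequence = NA_character_, description = "",
                       family = "", subgroup = "", cluster_ids = list(),
                       disintegrin_flag = FALSE, species = "") {
  stopifnot(is.character(record_id), length(record_id) == 1L,
            nzchar(record_id))
  if (!is.na(sequence)) {
    sequence <- toupper(sequence)
    if (!nzchar(sequence)) {
      stop("record '", record_id, "': empty sequence", call. = FALSE)
    }
    bad <- setdiff(strsplit(sequence, "")[[1]], AA_ALPHABET)
    if (length(bad) > 0L) {
      stop("record '", record_id, "': illegal residue character '",
           bad[[1]], "'", call. = FALSE)
    }
  }
  structure(list(record_id = record_id, description = description,
                 sequence = sequence, family = family, subgroup = subgroup,
                 cluster_ids = cluster_ids,
                 disintegrin_flag = isTRUE(disintegrin_flag),
                 species = species),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s> %s aa, family='%s'%s\n", x$record_id,
              if (is.na(x$sequence)) "?" else nchar(x$sequence), x$family,
              if (x$disintegrin_flag) ", disintegrin-flagged" else ""))
  invisible(x)
}

#' Read a FASTA file of amino-acid sequences
#'
#' The header token before the first whitespace becomes the record id; the
#' remainder becomes the description. Sequences are uppercased and
#' validated against the 20-letter amino-acid alphabet plus `X`; a record
#' containing any other character raises an error naming the record and
#' the character (fail-loud: invalid records are rejected, never skipped).
#'
#' @param path path to a FASTA file.
#' @return list of [seq_record()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  hdr <- grepl("^>", lines)
  if (!hdr[[1]]) stop("not FASTA: first line lacks '>' in ", path,
                      call. = FALSE)
  idx <- cumsum(hdr)
  out <- vector("list", sum(hdr))
  for (k in seq_len(sum(hdr))) {
    block <- lines[idx == k]
    header <- sub("^>", "", block[[1]])
    toks <- strsplit(trimws(header), "\\s+")[[1]]
    id <- toks[[1]]
    desc <- trimws(sub(paste0("^\\s*", gsub("([][{}()+*^$|\\\\?.])",
                                            "\\\\\\1", id)), "",
                       trimws(header)))
    seqs <- paste(block[-1], collapse = "")
    if (!nzchar(seqs)) {
      stop("record '", id, "': entry has no sequence lines", call. = FALSE)
    }
    out[[k]] <- seq_record(id, sequence = seqs, description = desc)
  }
  ids <- vapply(out, `[[`, "", "record_id")
  if (anyDuplicated(ids)) {
    stop("duplicate record_id in ", path, ": ", ids[duplicated(ids)][[1]],
         call. = FALSE)
  }
  out
}

#' Write sequence records as FASTA
#'
#' Inverse of [read_fasta()]: ids, order and sequences round-trip exactly.
#'
#' @param records list of [seq_record()].
#' @param path output path.
#' @param width sequence line width (0 = single line).
#' @export
write_fasta <- function(records, path, width = 60L) {
  lines <- unlist(lapply(records, function(r) {
    stopifnot(!is.na(r$sequence))
    hdr <- paste0(">", r$record_id,
                  if (nzchar(r$description)) paste0(" ", r$description) else "")
    body <- if (width > 0L) {
      starts <- seq(1L, nchar(r$sequence), by = width)
      substring(r$sequence, starts, pmin(starts + width - 1L,
                                         nchar(r$sequence)))
    } else r$sequence
    c(hdr, body)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Parse a cluster identifier of the form "<identity>-<index>"
#'
#' Database clusters are keyed by two numbers: the percent-identity
#' threshold at which the clustering was performed (25, 30, ..., 95) and
#' the 1-based cluster index at that threshold, sorted by decreasing
#' cluster abundance. A genus prefix (e.g. `"Amb-25-357"`) is tolerated
#' and ignored.
#'
#' @param text e.g. `"35-121"`.
#' @return list with integer fields `identity_threshold`, `cluster_index`,
#'   class `cluster_id`.
#' @export
parse_cluster_id <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  core <- sub("^[A-Za-z]+-", "", trimws(text))
  if (!grepl("^[0-9]+-[0-9]+$", core)) {
    stop("malformed cluster id: '", text, "'", call. = FALSE)
  }
  parts <- as.integer(strsplit(core, "-")[[1]])
  if (!(parts[[1]] %in% CLUSTER_THRESHOLDS)) {
    stop("cluster id '", text, "': identity threshold ", parts[[1]],
         " not in {", paste(CLUSTER_THRESHOLDS, collapse = ","), "}",
         call. = FALSE)
  }
  if (parts[[2]] < 1L) {
    stop("cluster id '", text, "': cluster index must be >= 1",
         call. = FALSE)
  }
  structure(list(identity_threshold = parts[[1]],
                 cluster_index = parts[[2]]), class = "cluster_id")
}

#' Format a cluster identifier
#' @param cid a `cluster_id` object.
#' @return the `"<identity>-<index>"` string.
#' @export
format_cluster_id <- function(cid) {
  stopifnot(inherits(cid, "cluster_id"))
  sprintf("%d-%d", cid$identity_threshold, cid$cluster_index)
}

# cell is "true-like" unless empty or an explicit negative
truthy_cell <- function(x) {
  x <- trimws(as.character(x))
  !is.na(x) & nzchar(x) &
    !(tolower(x) %in% c("0", "false", "f", "no", "na", "n"))
}

#' Read an annotation table (TSV or XLSX) into sequence records
#'
#' The table must have a header row. `column_map` names the columns of
#' interest; at minimum `id` and `family`. When a `disintegrin` column is
#' mapped, the flag is true iff the cell is non-empty and not an explicit
#' negative ("0", "false", "no", "na"). TSV is the canonical dialect;
#' `.xlsx` files are read through a minimal built-in worksheet reader.
#'
#' @param path path to a `.tsv`/`.txt` (tab-separated, header row) or
#'   `.xlsx` file.
#' @param column_map named list/character vector with entries `id`,
#'   `family`, and optionally `disintegrin`, `subgroup`, `species`,
#'   `sequence`. May also be the path of a key=value config file.
#' @return list of [seq_record()].
#' @export
read_annotation_table <- function(path, column_map) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.character(column_map) && length(column_map) == 1L &&
      file.exists(column_map)) {
    column_map <- read_kv_config(column_map)
  }
  column_map <- as.list(column_map)
  for (need in c("id", "family")) {
    if (is.null(column_map[[need]])) {
      stop("column_map lacks required entry '", need, "'", call. = FALSE)
    }
  }
  df <- if (grepl("\\.xlsx$", path, ignore.case = TRUE) || dir.exists(path)) {
    read_xlsx_sheet(path)
  } else {
    read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
               check.names = FALSE, quote = "", na.strings = NULL)
  }
  for (field in names(column_map)) {
    col <- column_map[[field]]
    if (!(col %in% names(df))) {
      stop("mapped column '", col, "' (for '", field, "') not found; ",
           "available headers: ", paste(names(df), collapse = ", "),
           call. = FALSE)
    }
  }
  pick <- function(field, default) {
    if (is.null(column_map[[field]])) rep(default, nrow(df))
    else trimws(df[[column_map[[field]]]])
  }
  ids <- trimws(df[[column_map$id]])
  fams <- pick("family", "")
  dis <- if (is.null(column_map$disintegrin)) rep(FALSE, nrow(df)) else
    truthy_cell(df[[column_map$disintegrin]])
  subs <- pick("subgroup", "")
  spec <- pick("species", "")
  seqs <- if (is.null(column_map$sequence)) rep(NA_character_, nrow(df)) else
    trimws(df[[column_map$sequence]])
  lapply(seq_len(nrow(df)), function(i) {
    seq_record(ids[[i]],
               sequence = if (is.na(seqs[[i]]) || !nzchar(seqs[[i]]))
                 NA_character_ else seqs[[i]],
               family = fams[[i]], subgroup = subs[[i]],
               disintegrin_flag = dis[[i]], species = spec[[i]])
  })
}

#' Tabulate records per family label
#'
#' Labels are compared after trimming whitespace, case-sensitively; blank
#' labels are tabulated as `"unannotated"`. The counts always sum to the
#' number of records.
#'
#' @param records list of [seq_record()].
#' @return object of class `family_table`: named integer vector `counts`
#'   plus `total`.
#' @export
family_counts <- function(records) {
  labs <- vapply(records, function(r) {
    f <- trimws(r$family)
    if (nzchar(f)) f else "unannotated"
  }, "")
  counts <- if (length(labs)) {
    tab <- table(labs)
    setNames(as.integer(tab), names(tab))[order(names(table(labs)))]
  } else {
    setNames(integer(), character())
  }
  structure(list(counts = counts, total = length(records)),
            class = "family_table")
}

#' @export
print.family_table <- function(x, ...) {
  cat(sprintf("<family_table> %d records, %d families\n", x$total,
              length(x$counts)))
  if (length(x$counts)) {
    print(sort(x$counts, decreasing = TRUE))
  }
  invisible(x)
}
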