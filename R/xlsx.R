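# Minimal XLSX support. No xlsx reader ships with this R stack, but an
# .xlsx file is a ZIP of XML parts, and xml2 + unzip are available:
# read_xlsx_sheet() extracts the first worksheet of a workbook into a
# character data.frame (header row = column names). write_xlsx_minimal()
# emits a store-only (uncompressed) single-sheet workbook with inline
# strings; it exists so the XLSX read path can be exercised from
# programmatically generated fixtures.

col_letter_to_index <- function(ref) {
  letters_part <- gsub("[0-9]", "", ref)
  chars <- utf8ToInt(letters_part) - utf8ToInt("A") + 1L
  Reduce(function(acc, d) acc * 26L + d, chars, accumulate = FALSE)
}

#' Read the first worksheet of an XLSX workbook
#'
#' Supports shared strings, inline strings and plain values; all cells are
#' returned as character. The first row supplies column names. `path` may
#' alternatively be a directory containing an already-extracted workbook.
#'
#' @param path `.xlsx` file (or extracted workbook directory).
#' @return data.frame of character columns.
#' @export
read_xlsx_sheet <- function(path) {
  if (dir.exists(path)) {
    root <- path
  } else {
    root <- tempfile("xlsx_")
    dir.create(root)
    on.exit(unlink(root, recursive = TRUE), add = TRUE)
    utils::unzip(path, exdir = root)
  }
  sheet_path <- file.path(root, "xl", "worksheets", "sheet1.xml")
  if (!file.exists(sheet_path)) {
    cand <- list.files(file.path(root, "xl", "worksheets"),
                       pattern = "\\.xml$", full.names = TRUE)
    if (length(cand) == 0L) stop("no worksheet found in ", path,
                                 call. = FALSE)
    sheet_path <- cand[[1]]
  }
  shared <- character()
  ss_path <- file.path(root, "xl", "sharedStrings.xml")
  if (file.exists(ss_path)) {
    ss <- xml2::read_xml(ss_path)
    shared <- vapply(xml2::xml_find_all(ss, ".//*[local-name()='si']"),
                     function(si) {
                       paste(xml2::xml_text(xml2::xml_find_all(
                         si, ".//*[local-name()='t']")), collapse = "")
                     }, "")
  }
  sheet <- xml2::read_xml(sheet_path)
  rows <- xml2::xml_find_all(sheet, ".//*[local-name()='row']")
  if (length(rows) == 0L) stop("worksheet has no rows: ", path,
                               call. = FALSE)
  cells <- lapply(rows, function(row) {
    cs <- xml2::xml_find_all(row, "./*[local-name()='c']")
    refs <- xml2::xml_attr(cs, "r")
    types <- xml2::xml_attr(cs, "t")
    vals <- vapply(seq_along(cs), function(i) {
      ty <- types[[i]]
      if (!is.na(ty) && ty == "inlineStr") {
        paste(xml2::xml_text(xml2::xml_find_all(
          cs[[i]], ".//*[local-name()='t']")), collapse = "")
      } else {
        v <- xml2::xml_find_first(cs[[i]], "./*[local-name()='v']")
        raw <- if (inherits(v, "xml_missing")) "" else xml2::xml_text(v)
        if (!is.na(ty) && ty == "s" && nzchar(raw)) {
          shared[[as.integer(raw) + 1L]]
        } else raw
      }
    }, "")
    list(col = vapply(refs, col_letter_to_index, 1L), val = vals)
  })
  ncol_out <- max(vapply(cells, function(x) {
    if (length(x$col)) max(x$col) else 0L
  }, 1L))
  mat <- matrix("", nrow = length(cells), ncol = ncol_out)
  for (i in seq_along(cells)) mat[i, cells[[i]]$col] <- cells[[i]]$val
  header <- mat[1, ]
  header[!nzchar(header)] <- paste0("V", which(!nzchar(header)))
  body <- mat[-1, , drop = FALSE]
  df <- as.data.frame(body, stringsAsFactors = FALSE)
  names(df) <- header
  df
}

# --- store-only ZIP writer (for fixture workbooks) ----------------------

# bitwShiftR treats its argument as an unsigned 32-bit value, which is
# exactly the logical right shift CRC-32 needs; 0xEDB88320 == -306674912L.
crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(-306674912L, bitwShiftR(c, 1))
      } else bitwShiftR(c, 1)
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(c, b), 255L)
    c <- bitwXor(crc32_table[idx + 1L], bitwShiftR(c, 8))
  }
  bitwXor(c, -1L)
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                            endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                            endian = "little")

zip_store <- function(files, out_path) {
  # files: named list name -> character content (UTF-8)
  con <- file(out_path, "wb")
  on.exit(close(con))
  entries <- list()
  offset <- 0L
  for (nm in names(files)) {
    data <- charToRaw(paste0(files[[nm]], ""))
    crc <- crc32(data)
    name_raw <- charToRaw(nm)
    local_hdr <- c(u32(0x04034b50L), u16(20L), u16(0L), u16(0L),
                   u16(0L), u16(0L), u32(crc), u32(length(data)),
                   u32(length(data)), u16(length(name_raw)), u16(0L))
    writeBin(c(local_hdr, name_raw, data), con)
    entries[[nm]] <- list(crc = crc, size = length(data), offset = offset)
    offset <- offset + length(local_hdr) + length(name_raw) + length(data)
  }
  cd_start <- offset
  cd_size <- 0L
  for (nm in names(files)) {
    e <- entries[[nm]]
    name_raw <- charToRaw(nm)
    hdr <- c(u32(0x02014b50L), u16(20L), u16(20L), u16(0L), u16(0L),
             u16(0L), u16(0L), u32(e$crc), u32(e$size), u32(e$size),
             u16(length(name_raw)), u16(0L), u16(0L), u16(0L), u16(0L),
             u32(0L), u32(e$offset))
    writeBin(c(hdr, name_raw), con)
    cd_size <- cd_size + length(hdr) + length(name_raw)
  }
  eocd <- c(u32(0x06054b50L), u16(0L), u16(0L), u16(length(files)),
            u16(length(files)), u32(cd_size), u32(cd_start), u16(0L))
  writeBin(eocd, con)
  invisible(out_path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a minimal single-sheet XLSX workbook
#'
#' Store-only ZIP, inline strings, no styles. Intended for generating
#' spreadsheet fixtures in tests; not a general-purpose writer.
#'
#' @param df data.frame (coerced to character).
#' @param path output `.xlsx` path.
#' @export
write_xlsx_minimal <- function(df, path) {
  col_ref <- function(j) {
    s <- ""
    while (j > 0L) {
      s <- paste0(LETTERS[(j - 1L) %% 26L + 1L], s)
      j <- (j - 1L) %/% 26L
    }
    s
  }
  all_rows <- rbind(names(df), as.matrix(
    as.data.frame(lapply(df, as.character), stringsAsFactors = FALSE)))
  row_xml <- vapply(seq_len(nrow(all_rows)), function(i) {
    cells <- vapply(seq_len(ncol(all_rows)), function(j) {
      v <- all_rows[i, j]
      if (is.na(v) || !nzchar(v)) return("")
      sprintf('<c r="%s%d" t="inlineStr"><is><t>%s</t></is></c>',
              col_ref(j), i, xml_escape(v))
    }, "")
    sprintf('<row r="%d">%s</row>', i, paste(cells, collapse = ""))
  }, "")
  sheet <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/',
    'spreadsheetml/2006/main"><sheetData>',
    paste(row_xml, collapse = ""), "</sheetData></worksheet>")
  files <- list(
    "[Content_Types].xml" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Types xmlns="http://schemas.openxmlformats.org/package/2006/',
      'content-types">',
      '<Default Extension="xml" ContentType="application/xml"/>',
      '<Default Extension="rels" ContentType="application/vnd.',
      'openxmlformats-package.relationships+xml"/>',
      '<Override PartName="/xl/workbook.xml" ContentType="application/',
      'vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
      '<Override PartName="/xl/worksheets/sheet1.xml" ContentType=',
      '"application/vnd.openxmlformats-officedocument.spreadsheetml.',
      'worksheet+xml"/></Types>'),
    "_rels/.rels" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/',
      '2006/relationships"><Relationship Id="rId1" Type="http://schemas.',
      'openxmlformats.org/officeDocument/2006/relationships/',
      'officeDocument" Target="xl/workbook.xml"/></Relationships>'),
    "xl/workbook.xml" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/',
      '2006/main" xmlns:r="http://schemas.openxmlformats.org/',
      'officeDocument/2006/relationships"><sheets>',
      '<sheet name="Sheet1" sheetId="1" r:id="rId1"/></sheets></workbook>'),
    "xl/_rels/workbook.xml.rels" = paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<Relationships xmlns="http://schemas.openxmlformats.org/package/',
      '2006/relationships"><Relationship Id="rId1" Type="http://schemas.',
      'openxmlformats.org/officeDocument/2006/relationships/worksheet" ',
      'Target="worksheets/sheet1.xml"/></Relationships>'),
    "xl/worksheets/sheet1.xml" = sheet)
  zip_store(files, path)
}
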