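# PDB-format structure models (AlphaFold-style: single conformer,
# per-residue pLDDT in the B-factor column), Kabsch superposition,
# coarse C-alpha secondary-structure assignment and family RMSD
# fingerprints.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Read a PDB-format structure model
#'
#' Fixed-column parsing of ATOM records (PDB v3.3 columns). Only the
#' first MODEL of a multi-model file is kept (predicted models are single
#' conformers). The element is inferred from the atom name when the
#' element columns are blank. Per-residue pLDDT is taken from the
#' B-factor of the C-alpha atom.
#'
#' @param path PDB file.
#' @param model_id id stored on the object (default: file base name).
#' @return object of class `pdb_model`: `atoms` data.frame (chain, resno,
#'   resname, atom, element, x, y, z, b) plus residue bookkeeping.
#' @export
read_pdb <- function(path, model_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  parse_pdb_lines(lines, model_id %||%
                    tools::file_path_sans_ext(basename(path)))
}

#' Parse PDB text already in memory
#' @param lines character vector of PDB lines (or one string with
#'   embedded newlines).
#' @param model_id id for the resulting model.
#' @return `pdb_model`, as [read_pdb()].
#' @export
parse_pdb_lines <- function(lines, model_id = "model") {
  if (length(lines) == 1L && grepl("\n", lines)) {
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  }
  # first MODEL only
  mstart <- grep("^MODEL", lines)
  if (length(mstart) > 0L) {
    mend <- grep("^ENDMDL", lines)
    end <- if (length(mend) > 0L) mend[[1]] else length(lines)
    lines <- lines[seq(mstart[[1]], end)]
  }
  sel <- grep("^ATOM  ", lines)
  if (length(sel) == 0L) stop("no ATOM records in PDB input",
                              call. = FALSE)
  fld <- function(ln, a, b) trimws(substr(ln, a, b))
  n <- length(sel)
  atoms <- data.frame(chain = character(n), resno = integer(n),
                      resname = character(n), atom = character(n),
                      element = character(n), x = numeric(n),
                      y = numeric(n), z = numeric(n), b = numeric(n),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ln <- lines[[sel[[i]]]]
    xyz <- suppressWarnings(as.numeric(c(fld(ln, 31, 38), fld(ln, 39, 46),
                                         fld(ln, 47, 54))))
    if (anyNA(xyz) || any(!is.finite(xyz))) {
      stop("non-numeric coordinates at line ", sel[[i]], call. = FALSE)
    }
    el <- fld(ln, 77, 78)
    name <- fld(ln, 13, 16)
    if (!nzchar(el)) el <- substr(gsub("[0-9]", "", name), 1L, 1L)
    atoms$chain[[i]] <- fld(ln, 22, 22)
    atoms$resno[[i]] <- as.integer(fld(ln, 23, 26))
    atoms$resname[[i]] <- fld(ln, 18, 20)
    atoms$atom[[i]] <- name
    atoms$element[[i]] <- toupper(el)
    atoms$x[[i]] <- xyz[[1]]
    atoms$y[[i]] <- xyz[[2]]
    atoms$z[[i]] <- xyz[[3]]
    atoms$b[[i]] <- suppressWarnings(as.numeric(fld(ln, 61, 66)))
  }
  atoms$b[is.na(atoms$b)] <- 0
  for (ch in unique(atoms$chain)) {
    rn <- unique(atoms$resno[atoms$chain == ch])
    if (any(diff(rn) <= 0L)) {
      stop("residue numbers not strictly increasing in chain '", ch, "'",
           call. = FALSE)
    }
  }
  structure(list(model_id = model_id, atoms = atoms),
            class = "pdb_model")
}

#' @export
print.pdb_model <- function(x, ...) {
  ch <- model_chains(x)
  cat(sprintf("<pdb_model %s> %d atoms, chains: %s\n", x$model_id,
              nrow(x$atoms), paste(ch, collapse = ",")))
  invisible(x)
}

#' Chains of a model, in order of first appearance
#' @param model `pdb_model`.
#' @return character vector of chain ids.
#' @export
model_chains <- function(model) unique(model$atoms$chain)

#' Residue table of one chain
#' @param model `pdb_model`.
#' @param chain chain id (default: first chain).
#' @return data.frame: resno, resname, has_ca, plddt (CA B-factor).
#' @export
model_residues <- function(model, chain = model_chains(model)[[1]]) {
  a <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  resno <- unique(a$resno)
  ca <- a[a$atom == "CA", , drop = FALSE]
  data.frame(
    resno = resno,
    resname = vapply(resno, function(r) a$resname[a$resno == r][[1]], ""),
    has_ca = resno %in% ca$resno,
    plddt = vapply(resno, function(r) {
      v <- ca$b[ca$resno == r]
      if (length(v)) v[[1]] else NA_real_
    }, 0),
    stringsAsFactors = FALSE)
}

#' One-letter sequence of a chain (unknown residues become X)
#' @inheritParams model_residues
#' @return character scalar.
#' @export
model_sequence <- function(model, chain = model_chains(model)[[1]]) {
  res <- model_residues(model, chain)
  letters1 <- AA3TO1[res$resname]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

#' C-alpha coordinate matrix of a chain
#' @inheritParams model_residues
#' @return n x 3 matrix with rownames = residue numbers (residues lacking
#'   a CA are omitted).
#' @export
model_ca <- function(model, chain = model_chains(model)[[1]]) {
  a <- model$atoms
  ca <- a[a$chain == chain & a$atom == "CA", , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resno
  m
}

#' Write a model as PDB text
#' @param model `pdb_model`.
#' @param path output path; `NULL` returns the lines invisibly.
#' @param ssbond optional bond data.frame from [detect_bonds()] output to
#'   emit as SSBOND header records.
#' @return path (or lines when `path` is NULL), invisibly.
#' @export
write_pdb <- function(model, path = NULL, ssbond = NULL) {
  a <- model$atoms
  hdr <- character()
  if (!is.null(ssbond) && nrow(ssbond)) {
    hdr <- vapply(seq_len(nrow(ssbond)), function(i) {
      sprintf("SSBOND %3d CYS %s %4d    CYS %s %4d %s %38.2f",
              i, ssbond$chain_a[[i]], ssbond$res_a[[i]],
              ssbond$chain_b[[i]], ssbond$res_b[[i]], "",
              ssbond$distance[[i]])
    }, "")
  }
  lines <- vapply(seq_len(nrow(a)), function(i) {
    name <- a$atom[[i]]
    name_f <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name_f, a$resname[[i]], a$chain[[i]], a$resno[[i]],
            a$x[[i]], a$y[[i]], a$z[[i]], 1.0, a$b[[i]], a$element[[i]])
  }, "")
  lines <- c(hdr, lines, "END")
  if (is.null(path)) return(invisible(lines))
  writeLines(lines, path)
  invisible(path)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `coords_mobile` onto `coords_ref` via
#' singular value decomposition of the cross-covariance matrix, with the
#' reflection corrected so the rotation is proper (det = +1). The
#' reported RMSD is minimal over all rigid motions.
#'
#' @param coords_ref,coords_mobile n x 3 matrices, n >= 3, paired rows.
#' @return list (class `superposition`): `rotation` 3x3, `translation`
#'   length-3, `rmsd`, `n_atoms`. Transformed mobile coordinates are
#'   `coords_mobile %*% rotation + translation` (rows).
#' @export
kabsch_superpose <- function(coords_ref, coords_mobile) {
  A <- as.matrix(coords_ref)
  B <- as.matrix(coords_mobile)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3L) {
    stop("coordinate sets must be equal-size n x 3 matrices",
         call. = FALSE)
  }
  n <- nrow(A)
  if (n < 3L) stop("need at least 3 paired atoms", call. = FALSE)
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca)
  B0 <- sweep(B, 2L, cb)
  s <- svd(crossprod(B0, A0))   # 3x3 cross-covariance B0' A0
  if (s$d[[2]] < 1e-9 * max(s$d[[1]], 1)) {
    stop("degenerate (collinear) coordinate set", call. = FALSE)
  }
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  Bfit <- B0 %*% R
  rmsd <- sqrt(sum((Bfit - A0)^2) / n)
  structure(list(rotation = R, translation = as.numeric(ca - cb %*% R),
                 rmsd = rmsd, n_atoms = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A over %d atoms\n", x$rmsd,
              x$n_atoms))
  invisible(x)
}

#' Default C-alpha secondary-structure thresholds
#'
#' P-SEA-style distance windows (Angstrom): a residue window is
#' helix-like when d(i,i+3) and d(i,i+4) fall in the helix ranges, and
#' strand-like when d(i,i+2) falls in the strand range. Helix segments
#' must span >= `helix_min_len` residues, strand segments >=
#' `strand_min_len`.
#'
#' @return named list of thresholds.
#' @export
sse_defaults <- function() {
  list(helix_d13 = c(5.0, 6.2), helix_d14 = c(5.9, 7.2),
       strand_d13 = c(6.2, 7.2), helix_min_len = 4L, strand_min_len = 3L)
}

#' Assign coarse secondary structure from C-alpha geometry
#'
#' Every residue of the chain gets one of H (helix), E (strand) or C
#' (coil). Residues lacking a C-alpha are forced to C. Helix assignment
#' wins over strand where windows overlap.
#'
#' @param model `pdb_model` (or an n x 3 CA matrix).
#' @param chain chain id.
#' @param config threshold list, see [sse_defaults()].
#' @return character vector over residues, values in {H,E,C}.
#' @export
assign_sse <- function(model, chain = NULL,
                       config = sse_defaults()) {
  if (is.matrix(model)) {
    ca <- model
    has_ca <- rep(TRUE, nrow(ca))
  } else {
    chain <- chain %||% model_chains(model)[[1]]
    res <- model_residues(model, chain)
    has_ca <- res$has_ca
    ca <- model_ca(model, chain)
  }
  n_res <- length(has_ca)
  if (sum(has_ca) < 5L) stop("chain needs >= 5 residues with C-alpha",
                             call. = FALSE)
  # index map: sse computed over CA-bearing residues, others coil
  d <- function(i, j) sqrt(sum((ca[i, ] - ca[j, ])^2))
  m <- nrow(ca)
  lab <- rep("C", m)
  in_rng <- function(v, rng) v >= rng[[1]] & v <= rng[[2]]
  hel_win <- rep(FALSE, m)
  for (i in seq_len(max(m - 4L, 0L))) {
    hel_win[i] <- in_rng(d(i, i + 3L), config$helix_d13) &&
      in_rng(d(i, i + 4L), config$helix_d14)
  }
  str_win <- rep(FALSE, m)
  for (i in seq_len(max(m - 2L, 0L))) {
    str_win[i] <- in_rng(d(i, i + 2L), config$strand_d13)
  }
  # the distance condition must hold at >= min_len consecutive window
  # starts; the marked segment covers the residues those windows span
  mark_runs <- function(win, span, min_len, sym) {
    r <- rle(win)
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$values)) {
      if (r$values[[k]] && r$lengths[[k]] >= min_len) {
        seg <- seq(pos[[k]], min(pos[[k]] + r$lengths[[k]] - 1L + span, m))
        lab[seg][lab[seg] == "C"] <<- sym
      }
    }
  }
  mark_runs(hel_win, 4L, config$helix_min_len, "H")  # helix wins overlaps
  mark_runs(str_win, 2L, config$strand_min_len, "E")
  out <- rep("C", n_res)
  out[has_ca] <- lab
  out
}

#' All-pairs RMSD fingerprint of a model family
#'
#' Models are paired by residue index (families are assumed alignable, so
#' members share length); superposition uses only residues assigned H or
#' E in every model, mirroring "secondary-structure element" alignment
#' statistics reported as `min–max ± sd`.
#'
#' @param models list of `pdb_model` (or CA matrices) of equal residue
#'   count.
#' @param sse_only restrict to residues helical/strand in all models.
#' @param config SSE thresholds, see [sse_defaults()].
#' @return object of class `rmsd_fingerprint`: n_models, n_pairs, min,
#'   max, mean, sd (Angstrom).
#' @export
fingerprint <- function(models, sse_only = TRUE, config = sse_defaults()) {
  if (length(models) < 2L) stop("need >= 2 models", call. = FALSE)
  cas <- lapply(models, function(m) if (is.matrix(m)) m else model_ca(m))
  ns <- vapply(cas, nrow, 1L)
  if (length(unique(ns)) != 1L) {
    stop("models differ in residue count: ", paste(ns, collapse = ","),
         call. = FALSE)
  }
  keep <- rep(TRUE, ns[[1]])
  if (sse_only) {
    for (ca in cas) {
      sse <- assign_sse(ca, config = config)
      keep <- keep & sse %in% c("H", "E")
    }
    if (!any(keep)) stop("no residues are secondary-structure in all ",
                         "models", call. = FALSE)
  }
  pairs <- utils::combn(length(cas), 2L)
  rmsds <- apply(pairs, 2L, function(p) {
    kabsch_superpose(cas[[p[[1]]]][keep, , drop = FALSE],
                     cas[[p[[2]]]][keep, , drop = FALSE])$rmsd
  })
  structure(list(n_models = length(cas), n_pairs = ncol(pairs),
                 n_residues = sum(keep), min = min(rmsds),
                 max = max(rmsds), mean = mean(rmsds),
                 sd = if (length(rmsds) > 1L) sd(rmsds) else 0),
            class = "rmsd_fingerprint")
}

#' @export
print.rmsd_fingerprint <- function(x, ...) {
  cat(sprintf(
    "<rmsd_fingerprint> %d models, %d pairs, %d residues: %.2f-%.2f A +/- %.2f A (mean %.2f)\n",
    x$n_models, x$n_pairs, x$n_residues, x$min, x$max, x$sd, x$mean))
  invisible(x)
}
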