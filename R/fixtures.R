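# Deterministic synthetic fixtures: every input kind the pipeline
# consumes (PDB models with engineered geometry, motif-bearing
# sequences, structural-search hit tables, annotation spreadsheets) can
# be generated in code from a seed. Same seed + parameters => identical
# bytes; the generators never touch the network or external files.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so fixture generation
#' never perturbs surrounding randomness.
#'
#' @param seed integer seed.
#' @param code expression.
#' @return value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Random amino-acid sequence (20-letter alphabet)
#' @param n length.
#' @param seed optional seed (uses current RNG when NULL).
#' @return character scalar.
#' @export
random_sequence <- function(n, seed = NULL) {
  gen <- function() paste(sample(AA20, n, replace = TRUE), collapse = "")
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# assemble a pdb_model from CA coordinates, a sequence, and optional SG
# atom coordinates for cysteines (named by residue number)
model_from_ca <- function(ca, sequence, sg = list(), chain = "A",
                          model_id = "fixture", plddt = 90.0,
                          resno_offset = 0L) {
  stopifnot(nrow(ca) == nchar(sequence))
  letters1 <- strsplit(sequence, "")[[1]]
  aa3 <- setNames(names(AA3TO1), AA3TO1)
  rows <- list()
  for (i in seq_len(nrow(ca))) {
    resname <- aa3[letters1[[i]]]
    if (is.na(resname)) resname <- "UNK"
    resno <- i + resno_offset
    rows[[length(rows) + 1L]] <- data.frame(
      chain = chain, resno = resno, resname = resname, atom = "CA",
      element = "C", x = ca[i, 1], y = ca[i, 2], z = ca[i, 3],
      b = plddt, stringsAsFactors = FALSE)
    key <- as.character(resno)
    if (resname == "CYS" && !is.null(sg[[key]])) {
      s <- sg[[key]]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = resno, resname = "CYS", atom = "SG",
        element = "S", x = s[[1]], y = s[[2]], z = s[[3]], b = plddt,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(model_id = model_id, atoms = do.call(rbind, rows)),
            class = "pdb_model")
}

combine_models <- function(models, model_id = "multimer") {
  structure(list(model_id = model_id,
                 atoms = do.call(rbind, lapply(models, `[[`, "atoms"))),
            class = "pdb_model")
}

pdb_text <- function(model) paste(write_pdb(model), collapse = "\n")

#' Ideal alpha-helix C-alpha trace
#' @param n residues.
#' @param rise rise per residue (Angstrom).
#' @param twist turn per residue (degrees).
#' @param radius helix radius (Angstrom).
#' @return n x 3 matrix.
#' @export
helix_ca <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  t <- (seq_len(n) - 1L) * twist * pi / 180
  cbind(radius * cos(t), radius * sin(t), (seq_len(n) - 1L) * rise)
}

#' Ideal extended-strand C-alpha trace (zigzag, ~3.8 A spacing)
#' @param n residues.
#' @return n x 3 matrix.
#' @export
strand_ca <- function(n) {
  i <- seq_len(n) - 1L
  dx <- 3.35
  dz <- sqrt(3.8^2 - dx^2)
  cbind(i * dx, rep(0, n), ifelse(i %% 2L == 0L, 0, dz))
}

#' Self-avoiding random-walk C-alpha trace (coil decoy)
#'
#' Steps of 3.8 A in uniformly random directions, rejecting any step that
#' brings the new point within `min_sep` of a non-adjacent predecessor.
#'
#' @param n residues.
#' @param seed seed.
#' @param min_sep self-avoidance distance (Angstrom).
#' @return n x 3 matrix.
#' @export
coil_walk_ca <- function(n, seed, min_sep = 4.0) {
  with_seed(seed, {
    pts <- matrix(0, n, 3)
    for (i in 2:n) {
      for (try in 1:200) {
        v <- rnorm(3)
        step <- 3.8 * v / sqrt(sum(v^2))
        cand <- pts[i - 1L, ] + step
        prev <- pts[seq_len(max(i - 2L, 0L)), , drop = FALSE]
        if (nrow(prev) == 0L ||
            min(sqrt(rowSums(sweep(prev, 2L, cand)^2))) >= min_sep) {
          pts[i, ] <- cand
          break
        }
        if (try == 200L) stop("self-avoiding walk got stuck",
                              call. = FALSE)
      }
    }
    pts
  })
}

#' Helix fixture as PDB text
#' @param n residues (poly-alanine).
#' @param sequence optional sequence overriding poly-A (length n).
#' @return PDB text (single string).
#' @export
make_helix <- function(n = 20L, sequence = NULL) {
  seqs <- sequence %||% strrep("A", n)
  pdb_text(model_from_ca(helix_ca(nchar(seqs)), seqs,
                         model_id = "helix"))
}

#' Strand fixture as PDB text
#' @inheritParams make_helix
#' @return PDB text.
#' @export
make_strand <- function(n = 12L, sequence = NULL) {
  seqs <- sequence %||% strrep("A", n)
  pdb_text(model_from_ca(strand_ca(nchar(seqs)), seqs,
                         model_id = "strand"))
}

#' Random-coil fixture as PDB text
#' @param n residues.
#' @param seed seed.
#' @return PDB text.
#' @export
make_coil <- function(n = 30L, seed = 1L) {
  pdb_text(model_from_ca(coil_walk_ca(n, seed), strrep("A", n),
                         model_id = "coil"))
}

# interpolate spacer CA positions between anchors, keeping consecutive
# spacing near 3.8 A with a small deterministic zigzag
chain_through <- function(anchors) {
  pts <- anchors[1, , drop = FALSE]
  anchor_idx <- 1L
  for (k in 2:nrow(anchors)) {
    a <- anchors[k - 1L, ]
    b <- anchors[k, ]
    d <- sqrt(sum((b - a)^2))
    m <- max(1L, ceiling(d / 3.6))
    v <- (b - a) / d
    perp <- if (abs(v[[3]]) < 0.9) {
      w <- c(-v[[2]], v[[1]], 0)
      w / sqrt(sum(w^2))
    } else c(1, 0, 0)
    for (s in seq_len(m)) {
      p <- a + v * d * s / m
      if (s < m) p <- p + perp * 0.9 * ((s %% 2L) * 2L - 1L)
      pts <- rbind(pts, p)
    }
    anchor_idx <- c(anchor_idx, nrow(pts))
  }
  list(pts = pts, anchor_idx = anchor_idx)
}

#' Cysteine-topology structure fixture
#'
#' Builds a single-chain model with `n_cys` cysteines whose SG atoms
#' realise the requested pairwise distances exactly (within 1e-6 A):
#' pairs listed in `pairs` sit at their requested distance, every other
#' SG-SG distance is at least 8 A. Spacer residues keep consecutive
#' C-alpha spacing chemically plausible (~3.8 A).
#'
#' @param pairs list of `c(ordinal_a, ordinal_b, distance)` triples.
#' @param n_cys total cysteines (ordinals are sequence order).
#' @param seed seed (orients the SG-SG axes).
#' @return PDB text.
#' @export
make_cys_structure <- function(pairs, n_cys, seed = 1L) {
  for (p in pairs) {
    stopifnot(length(p) == 3L, p[[1]] >= 1L, p[[2]] >= 1L,
              p[[1]] <= n_cys, p[[2]] <= n_cys, p[[3]] > 0)
  }
  paired <- unlist(lapply(pairs, function(p) p[1:2]))
  if (anyDuplicated(paired)) {
    stop("a cysteine ordinal appears in two pairs", call. = FALSE)
  }
  with_seed(seed, {
    sg_pos <- matrix(NA_real_, n_cys, 3)
    ca_anchor <- matrix(NA_real_, n_cys, 3)
    # SG pair axes are drawn from the signed coordinate axes so that the
    # PDB text (3-decimal columns) reproduces requested distances exactly
    # whenever distance/2 has at most 3 decimals
    axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
    for (k in seq_along(pairs)) {
      p <- pairs[[k]]
      center <- c(14 * (k - 1L), 0, 0)
      u <- axes[sample(6L, 1L), ]
      sg_pos[p[[1]], ] <- center - u * p[[3]] / 2
      sg_pos[p[[2]], ] <- center + u * p[[3]] / 2
      ca_anchor[p[[1]], ] <- center - u * (p[[3]] / 2 + 2.4)
      ca_anchor[p[[2]], ] <- center + u * (p[[3]] / 2 + 2.4)
    }
    lone <- setdiff(seq_len(n_cys), paired)
    for (j in seq_along(lone)) {
      q <- c(14 * (length(pairs) + j - 1L), 0, 30)
      sg_pos[lone[[j]], ] <- q
      ca_anchor[lone[[j]], ] <- q + c(0, 0, 2.4)
    }
    # verify placement feasibility: unpaired SG-SG separations >= 8 A
    for (i in seq_len(n_cys - 1L)) {
      for (j in seq((i + 1L), n_cys)) {
        is_pair <- any(vapply(pairs, function(p) {
          all(sort(p[1:2]) == c(i, j))
        }, TRUE))
        dd <- sqrt(sum((sg_pos[i, ] - sg_pos[j, ])^2))
        if (!is_pair && dd < 8) {
          stop("impossible placement: non-paired SG atoms ", i, ",", j,
               " only ", round(dd, 2), " A apart", call. = FALSE)
        }
      }
    }
    path <- chain_through(ca_anchor)
    n_res <- nrow(path$pts)
    letters1 <- rep("A", n_res)
    letters1[path$anchor_idx] <- "C"
    sg <- setNames(lapply(seq_len(n_cys), function(i) sg_pos[i, ]),
                   as.character(path$anchor_idx))
    pdb_text(model_from_ca(path$pts, paste(letters1, collapse = ""),
                           sg = sg, model_id = "cys_fixture"))
  })
}

#' Hairpin disintegrin fixture
#'
#' A compact globular body with a two-armed antiparallel hairpin
#' sticking out of it; the triad sits at the apex and the flanking
#' cysteines (at `flank_offset` residues from the triad on each arm)
#' carry SG atoms `sg_dist` apart, so the stabilising bridge is detected.
#'
#' @param triad 3-letter triad (default RGD).
#' @param arm_len residues per arm (>= 5).
#' @param flank_offset cysteine offset from the triad (<= arm_len).
#' @param seed seed (body orientation only; geometry is deterministic).
#' @param sg_dist SG-SG distance of the flank pair (Angstrom).
#' @param bury place the triad inside the body instead (negative
#'   control: same sequence, no protrusion).
#' @return list: `pdb` (text), `sequence`, `triad_start`.
#' @export
make_hairpin <- function(triad = "RGD", arm_len = 8L, flank_offset = 4L,
                         seed = 1L, sg_dist = 2.05, bury = FALSE) {
  stopifnot(arm_len >= 5L, flank_offset <= arm_len, flank_offset >= 1L,
            nchar(triad) == 3L)
  # body: serpentine walk over a 4x4x3 grid, 3.8 A spacing
  grid <- expand.grid(x = 0:3, y = 0:3, z = 0:2)
  o <- order(grid$z, grid$y, ifelse(grid$y %% 2 == 0, grid$x, -grid$x))
  body <- as.matrix(grid[o, ]) * 3.8
  nb <- nrow(body)
  top <- body[nb, ]
  gap <- 5.0   # inter-arm distance
  up <- cbind(top[[1]], top[[2]] + seq_len(arm_len) * 0,
              top[[3]] + seq_len(arm_len) * 3.2)
  apex_z <- top[[3]] + (arm_len + 1L) * 3.2
  tri <- rbind(c(top[[1]] - 1.5, top[[2]], apex_z),
               c(top[[1]] + gap / 2, top[[2]] + 1.5, apex_z + 2.0),
               c(top[[1]] + gap + 1.5, top[[2]], apex_z))
  down <- cbind(top[[1]] + gap, top[[2]] + rev(seq_len(arm_len)) * 0,
                top[[3]] + rev(seq_len(arm_len)) * 3.2)
  if (bury) {
    # park the hairpin atoms inside the body envelope instead
    center <- colMeans(body)
    squash <- function(m) {
      sweep(sweep(m, 2L, c(top[[1]], top[[2]], top[[3]])), 1L,
            rep(0.12, nrow(m)), `*`) +
        matrix(center, nrow(m), 3, byrow = TRUE)
    }
    up <- squash(up); tri <- squash(tri); down <- squash(down)
  }
  ca <- rbind(body, up, tri, down)
  triad_start <- nb + arm_len + 1L
  seq_chars <- c(rep("A", nb), rep("S", arm_len),
                 strsplit(triad, "")[[1]], rep("S", arm_len))
  cys_before <- triad_start - flank_offset
  cys_after <- triad_start + 2L + flank_offset
  seq_chars[c(cys_before, cys_after)] <- "C"
  # staple: SG midway between the two flank CAs, sg_dist apart
  mid <- (ca[cys_before, ] + ca[cys_after, ]) / 2
  axis <- ca[cys_after, ] - ca[cys_before, ]
  axis <- axis / sqrt(sum(axis^2))
  sg <- list()
  sg[[as.character(cys_before)]] <- mid - axis * sg_dist / 2
  sg[[as.character(cys_after)]] <- mid + axis * sg_dist / 2
  model <- model_from_ca(ca, paste(seq_chars, collapse = ""), sg = sg,
                         model_id = if (bury) "buried_triad" else
                           "hairpin")
  list(pdb = pdb_text(model), sequence = paste(seq_chars, collapse = ""),
       triad_start = triad_start)
}

#' Helix-embedded triad decoy
#'
#' The triad and flanking cysteines sit mid-helix: the motif matches in
#' sequence, the cysteines are too far apart to bond, and nothing
#' protrudes.
#'
#' @param triad triad string.
#' @param n helix length.
#' @return list: `pdb`, `sequence`, `triad_start`.
#' @export
make_helix_decoy <- function(triad = "RGD", n = 31L) {
  mid <- (n - 1L) %/% 2L
  seq_chars <- rep("A", n)
  seq_chars[mid:(mid + 2L)] <- strsplit(triad, "")[[1]]
  seq_chars[c(mid - 4L, mid + 6L)] <- "C"
  ca <- helix_ca(n)
  sg <- list()
  for (p in c(mid - 4L, mid + 6L)) {
    sg[[as.character(p)]] <- ca[p, ] + c(0, 0, 1.8)
  }
  model <- model_from_ca(ca, paste(seq_chars, collapse = ""), sg = sg,
                         model_id = "helix_decoy")
  list(pdb = pdb_text(model), sequence = paste(seq_chars, collapse = ""),
       triad_start = mid)
}

#' Jittered family of models
#'
#' Copies of a base model with i.i.d. Gaussian noise added to every atom
#' coordinate; at sigma <= 0.3 A the disulfide topology is preserved by
#' construction margin (bonded SG pairs sit ~2 A apart versus a 3 A
#' cutoff and >= 8 A to any other SG).
#'
#' @param base_pdb base model PDB text (or `pdb_model`).
#' @param n number of models.
#' @param sigma noise sd per coordinate (Angstrom).
#' @param seed seed.
#' @return list of PDB texts.
#' @export
make_family <- function(base_pdb, n = 10L, sigma = 0.3, seed = 1L) {
  stopifnot(sigma >= 0)
  base <- if (inherits(base_pdb, "pdb_model")) base_pdb else
    parse_pdb_lines(base_pdb, "family_base")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      m <- base
      na <- nrow(m$atoms)
      m$atoms$x <- m$atoms$x + rnorm(na, 0, sigma)
      m$atoms$y <- m$atoms$y + rnorm(na, 0, sigma)
      m$atoms$z <- m$atoms$z + rnorm(na, 0, sigma)
      m$model_id <- sprintf("%s_%02d", base$model_id, i)
      pdb_text(m)
    })
  })
}

#' Homodimer fixture with one inter-chain disulfide
#'
#' Two copies of a chain carrying `n_cys` cysteines; the bridging
#' ordinal's SG atoms from the two chains are placed `sg_dist` apart, all
#' other SGs far apart.
#'
#' @param n_cys cysteines per chain.
#' @param bridge_ordinal which ordinal bridges the chains (e.g. the
#'   C-terminal reactive cysteine).
#' @param sg_dist inter-chain SG-SG distance.
#' @param seed seed.
#' @return PDB text (chains A and B).
#' @export
make_homodimer <- function(n_cys = 7L, bridge_ordinal = 7L,
                           sg_dist = 2.05, seed = 1L) {
  make_dimer(pairs_a = cbind(seq_len(n_cys)[0], seq_len(n_cys)[0]),
             bridges = rbind(c(bridge_ordinal, bridge_ordinal)),
             n_cys = n_cys, sg_dist = sg_dist, seed = seed)
}

#' Two-chain fixture with arbitrary inter-chain bridges
#'
#' @param pairs_a unused placeholder for future intra-chain bonds.
#' @param bridges matrix of (ordinal in A, ordinal in B) rows.
#' @param n_cys cysteines per chain.
#' @param sg_dist SG-SG distance for each bridge.
#' @param seed seed.
#' @return PDB text (chains A and B).
#' @export
make_dimer <- function(pairs_a = NULL, bridges, n_cys = 8L,
                       sg_dist = 2.05, seed = 1L) {
  bridges <- as.matrix(bridges)
  with_seed(seed, {
    build_chain <- function(chain, base_y) {
      # anchors on a line, 12 A apart; SG placed later
      anchors <- cbind(12 * (seq_len(n_cys) - 1L), base_y, 0)
      path <- chain_through(anchors)
      letters1 <- rep("A", nrow(path$pts))
      letters1[path$anchor_idx] <- "C"
      list(path = path, seq = paste(letters1, collapse = ""))
    }
    a <- build_chain("A", 0)
    b <- build_chain("B", 40)
    sg_a <- list()
    sg_b <- list()
    # default: each SG next to its CA, far from everything else
    for (i in seq_len(n_cys)) {
      sg_a[[as.character(a$path$anchor_idx[[i]])]] <-
        a$path$pts[a$path$anchor_idx[[i]], ] + c(0, 2.4, 0)
      sg_b[[as.character(b$path$anchor_idx[[i]])]] <-
        b$path$pts[b$path$anchor_idx[[i]], ] + c(0, 2.4, 0)
    }
    # bridges: place the two SGs midway between chains, sg_dist apart,
    # separated along x per bridge to keep bridges > 8 A from each other
    for (k in seq_len(nrow(bridges))) {
      oa <- bridges[k, 1]
      ob <- bridges[k, 2]
      center <- c(12 * (oa - 1L) + 3 * (k - 1L), 20, 10 * k)
      sg_a[[as.character(a$path$anchor_idx[[oa]])]] <-
        center - c(0, sg_dist / 2, 0)
      sg_b[[as.character(b$path$anchor_idx[[ob]])]] <-
        center + c(0, sg_dist / 2, 0)
    }
    ma <- model_from_ca(a$path$pts, a$seq, sg = sg_a, chain = "A",
                        model_id = "dimer")
    mb <- model_from_ca(b$path$pts, b$seq, sg = sg_b, chain = "B",
                        model_id = "dimer")
    pdb_text(combine_models(list(ma, mb), "dimer"))
  })
}

#' Synthetic structural-search hit table
#'
#' @param rows data.frame with columns query_id, target_pdb, z, rmsd,
#'   lali, pct_id, description.
#' @param path output path (TSV); `NULL` returns the text.
#' @return path, or the table text when `path` is NULL.
#' @export
make_dali_table <- function(rows, path = NULL) {
  need <- c("query_id", "target_pdb", "z", "rmsd", "lali", "pct_id",
            "description")
  stopifnot(all(need %in% names(rows)))
  txt <- c(paste(need, collapse = "\t"),
           vapply(seq_len(nrow(rows)), function(i) {
             paste(vapply(need, function(cl) as.character(rows[i, cl]),
                          ""), collapse = "\t")
           }, ""))
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(path)
}

#' Synthetic annotation table (TSV or XLSX)
#'
#' One row per record: id, family label, optional disintegrin-motif cell.
#'
#' @param families character vector, one family label per record
#'   (`""` = unannotated).
#' @param disintegrin character vector of motif cells (`""` = empty), or
#'   NULL for none.
#' @param path output path; extension `.xlsx` selects the spreadsheet
#'   writer, anything else TSV.
#' @param ids record ids (default SYN00001...).
#' @return path, invisibly.
#' @export
make_annotation_table <- function(families, disintegrin = NULL, path,
                                  ids = NULL) {
  n <- length(families)
  ids <- ids %||% sprintf("SYN%05d", seq_len(n))
  df <- data.frame(Accession = ids, Family = families,
                   stringsAsFactors = FALSE)
  if (!is.null(disintegrin)) df$`Disintegrin motif` <- disintegrin
  if (grepl("\\.xlsx$", path)) {
    write_xlsx_minimal(df, path)
  } else {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' The 137-row reclassification scenario as a synthetic hit table
#'
#' Generates one query per row split across four outcomes (94 matching a
#' mite-allergen fold, 32 a bacterial pore-forming toxin, 2 a
#' sulfotransferase, 9 without significant matches) together with the
#' corresponding records, as a checksum scenario for the rule engine's
#' partition property.
#'
#' @param counts named integer vector (der_f7, pore, sulfo, none).
#' @param seed seed for Z-score draws within each band.
#' @return list: `records`, `hits` (data.frame).
#' @export
make_partition_scenario <- function(counts = c(der_f7 = 94L, pore = 32L,
                                               sulfo = 2L, none = 9L),
                                    seed = 1L) {
  with_seed(seed, {
    total <- sum(counts)
    ids <- sprintf("CTX%03d", seq_len(total))
    specs <- rep(names(counts), counts)
    rows <- lapply(seq_len(total), function(i) {
      tgt <- switch(specs[[i]],
        der_f7 = list(pdb = "5wcx-A", z = runif(1, 10.5, 16),
                      desc = "DER F 7 allergen"),
        pore = list(pdb = "3zjx-A", z = runif(1, 10, 16),
                    desc = "EPSILON-TOXIN"),
        sulfo = list(pdb = "1q44-A", z = runif(1, 4, 7.5),
                     desc = "protein tyrosine sulfotransferase"),
        none = list(pdb = "9xyz-A", z = runif(1, 0.2, 1.9),
                    desc = "hypothetical protein"))
      data.frame(query_id = ids[[i]], target_pdb = tgt$pdb,
                 z = round(tgt$z, 1), rmsd = round(runif(1, 1.5, 3.5), 1),
                 lali = sample(60:140, 1), pct_id = round(runif(1, 5, 25), 1),
                 description = tgt$desc, stringsAsFactors = FALSE)
    })
    records <- lapply(ids, function(id) {
      seq_record(id, sequence = random_sequence(40), family = "Cytotoxin")
    })
    list(records = records, hits = do.call(rbind, rows))
  })
}
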