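# Disulfide-bond detection and connectivity notation. A bond is called
# when two cysteine SG (gamma sulfur) atoms lie closer than the cutoff
# (default 3.0 Angstrom); methionine SD atoms are deliberately excluded.
# Cysteines are numbered per chain by sequence-order ordinals (C1, C2,
# ...). Three notations are supported: dash ("C1-C6, C2-C4"), pipe
# ("|C:1 C:3 |C:2 C:5") and chain-qualified inter-chain ("A:1|B:8").

#' Detect disulfide bonds in a structure model
#'
#' All SG-SG pairs (intra- and inter-chain) below `cutoff` are candidate
#' bonds; conflicts (one SG within cutoff of several partners) are
#' resolved by greedy ascending-distance matching with each SG used at
#' most once (`method = "maxweight"` instead maximises bond count, then
#' minimises total distance, by exhaustive matching — feasible for the
#' small cysteine counts of these proteins). Cysteines without a partner
#' (or without an SG atom at all) are listed free.
#'
#' @param model `pdb_model`.
#' @param cutoff_angstrom SG-SG distance cutoff in Angstrom.
#' @param method conflict resolution: `"greedy"` or `"maxweight"`.
#' @param plddt_min optional pLDDT floor; cysteines on residues below it
#'   are ignored entirely.
#' @return object of class `disulfide_topology`: `sites` (chain, resno,
#'   ordinal, has_sg), `bonds` (chain/res/ordinal pairs + distance),
#'   `free` (unbonded SG-bearing sites).
#' @export
detect_bonds <- function(model, cutoff_angstrom = 3.0,
                         method = c("greedy", "maxweight"),
                         plddt_min = NULL) {
  stopifnot(cutoff_angstrom > 0)
  method <- match.arg(method)
  a <- model$atoms
  sites <- NULL
  for (ch in model_chains(model)) {
    res <- model_residues(model, ch)
    cys <- res[res$resname == "CYS", , drop = FALSE]
    if (!is.null(plddt_min)) {
      cys <- cys[is.na(cys$plddt) | cys$plddt >= plddt_min, ,
                 drop = FALSE]
    }
    if (nrow(cys) == 0L) next
    sg <- a[a$chain == ch & a$resname == "CYS" & a$atom == "SG", ,
            drop = FALSE]
    cys$ordinal <- seq_len(nrow(cys))
    cys$has_sg <- cys$resno %in% sg$resno
    cys$chain <- ch
    sites <- rbind(sites, cys[, c("chain", "resno", "ordinal", "has_sg")])
  }
  if (is.null(sites)) {
    sites <- data.frame(chain = character(), resno = integer(),
                        ordinal = integer(), has_sg = logical())
  }
  if (any(!sites$has_sg)) {
    warning(sum(!sites$has_sg), " cysteine(s) lack an SG atom; counted ",
            "free", call. = FALSE)
  }
  sg_sites <- sites[sites$has_sg, , drop = FALSE]
  sgxyz <- t(vapply(seq_len(nrow(sg_sites)), function(i) {
    row <- a[a$chain == sg_sites$chain[[i]] &
               a$resno == sg_sites$resno[[i]] & a$atom == "SG", ,
             drop = FALSE]
    c(row$x[[1]], row$y[[1]], row$z[[1]])
  }, numeric(3)))
  n <- nrow(sg_sites)
  cand <- NULL
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        dd <- sqrt(sum((sgxyz[i, ] - sgxyz[j, ])^2))
        if (dd < cutoff_angstrom) {
          cand <- rbind(cand, data.frame(i = i, j = j, distance = dd))
        }
      }
    }
  }
  chosen <- integer(0)
  if (!is.null(cand)) {
    if (method == "greedy") {
      cand <- cand[order(cand$distance), , drop = FALSE]
      used <- logical(n)
      for (k in seq_len(nrow(cand))) {
        if (!used[cand$i[[k]]] && !used[cand$j[[k]]]) {
          chosen <- c(chosen, k)
          used[cand$i[[k]]] <- used[cand$j[[k]]] <- TRUE
        }
      }
    } else {
      chosen <- max_matching(cand, n)
    }
  }
  bonds <- if (length(chosen)) {
    data.frame(
      chain_a = sg_sites$chain[cand$i[chosen]],
      res_a = sg_sites$resno[cand$i[chosen]],
      ordinal_a = sg_sites$ordinal[cand$i[chosen]],
      chain_b = sg_sites$chain[cand$j[chosen]],
      res_b = sg_sites$resno[cand$j[chosen]],
      ordinal_b = sg_sites$ordinal[cand$j[chosen]],
      distance = cand$distance[chosen], stringsAsFactors = FALSE)
  } else {
    data.frame(chain_a = character(), res_a = integer(),
               ordinal_a = integer(), chain_b = character(),
               res_b = integer(), ordinal_b = integer(),
               distance = numeric(), stringsAsFactors = FALSE)
  }
  bonded_key <- c(paste(bonds$chain_a, bonds$res_a),
                  paste(bonds$chain_b, bonds$res_b))
  free <- sites[sites$has_sg &
                  !(paste(sites$chain, sites$resno) %in% bonded_key) |
                  !sites$has_sg, , drop = FALSE]
  rownames(bonds) <- rownames(free) <- rownames(sites) <- NULL
  structure(list(model_id = model$model_id, sites = sites,
                 bonds = bonds[order(bonds$ordinal_a), , drop = FALSE],
                 free = free, cutoff = cutoff_angstrom),
            class = "disulfide_topology")
}

# exhaustive maximum matching: maximise bond count, break ties on total
# distance; candidate counts here are tiny (<= ~20 cysteines)
max_matching <- function(cand, n) {
  best <- list(score = -1, dist = Inf, sel = integer(0))
  recurse <- function(k, used, sel, dist) {
    if (k > nrow(cand)) {
      score <- length(sel)
      if (score > best$score ||
          (score == best$score && dist < best$dist)) {
        best <<- list(score = score, dist = dist, sel = sel)
      }
      return(invisible())
    }
    i <- cand$i[[k]]; j <- cand$j[[k]]
    if (!used[i] && !used[j]) {
      used[i] <- used[j] <- TRUE
      recurse(k + 1L, used, c(sel, k), dist + cand$distance[[k]])
      used[i] <- used[j] <- FALSE
    }
    recurse(k + 1L, used, sel, dist)
  }
  recurse(1L, logical(n), integer(0), 0)
  best$sel
}

#' @export
print.disulfide_topology <- function(x, ...) {
  cat(sprintf("<disulfide_topology %s> %d bond(s), %d free of %d cys\n",
              x$model_id, nrow(x$bonds), nrow(x$free), nrow(x$sites)))
  if (nrow(x$bonds)) cat(" ", notation_dash(x), "\n")
  invisible(x)
}

intra_bonds <- function(topology) {
  b <- topology$bonds
  b[b$chain_a == b$chain_b, , drop = FALSE]
}

#' Inter-chain (dimer) bonds of a topology
#' @param topology `disulfide_topology`.
#' @return bond rows joining different chains.
#' @export
interchain_bonds <- function(topology) {
  b <- topology$bonds
  b[b$chain_a != b$chain_b, , drop = FALSE]
}

#' Dash notation for intra-chain connectivity ("C1-C6, C2-C4, C3-C5")
#' @param topology `disulfide_topology`.
#' @return character scalar (`""` when there are no intra-chain bonds).
#' @export
notation_dash <- function(topology) {
  b <- intra_bonds(topology)
  if (nrow(b) == 0L) return("")
  lo <- pmin(b$ordinal_a, b$ordinal_b)
  hi <- pmax(b$ordinal_a, b$ordinal_b)
  o <- order(lo)
  paste(sprintf("C%d-C%d", lo[o], hi[o]), collapse = ", ")
}

#' Pipe notation for intra-chain connectivity ("|C:1 C:3 |C:2 C:5")
#' @param topology `disulfide_topology`.
#' @return character scalar.
#' @export
notation_pipe <- function(topology) {
  b <- intra_bonds(topology)
  if (nrow(b) == 0L) return("")
  lo <- pmin(b$ordinal_a, b$ordinal_b)
  hi <- pmax(b$ordinal_a, b$ordinal_b)
  o <- order(lo)
  paste(sprintf("|C:%d C:%d", lo[o], hi[o]), collapse = " ")
}

#' Chain-qualified notation for inter-chain bonds ("A:7|B:7")
#' @param topology `disulfide_topology`.
#' @return character scalar listing inter-chain bonds, comma separated.
#' @export
notation_interchain <- function(topology) {
  b <- interchain_bonds(topology)
  if (nrow(b) == 0L) return("")
  paste(sprintf("%s:%d|%s:%d", b$chain_a, b$ordinal_a, b$chain_b,
                b$ordinal_b), collapse = ", ")
}

#' Parse a connectivity notation into an ordinal bond set
#'
#' Accepts dash notation (`"C1-C6, C2-C4"`; hyphen or en-dash), pipe
#' notation (`"|C:1 C:3 |C:2 C:5"`), and chain-qualified inter-chain
#' pairs (`"A:1|B:8, A:8|B:1"`). Ordinal reuse within a chain is an
#' error.
#'
#' @param text notation string.
#' @return data.frame with columns `chain_a`, `ordinal_a`, `chain_b`,
#'   `ordinal_b` (chains `NA` for unqualified notations), normalized so
#'   ordinal_a <= ordinal_b within a chain and sorted.
#' @export
parse_notation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- gsub("–", "-", trimws(text))   # en-dash -> hyphen
  if (!nzchar(txt)) {
    return(data.frame(chain_a = character(), ordinal_a = integer(),
                      chain_b = character(), ordinal_b = integer(),
                      stringsAsFactors = FALSE))
  }
  pairs <- NULL
  if (grepl("^\\|", txt)) {
    toks <- strsplit(txt, "\\|")[[1]]
    toks <- trimws(toks[nzchar(trimws(toks))])
    for (tk in toks) {
      m <- regmatches(tk, regexec("^C:([0-9]+)\\s+C:([0-9]+)$", tk))[[1]]
      if (length(m) != 3L) stop("malformed pipe token: '", tk, "'",
                                call. = FALSE)
      pairs <- rbind(pairs, data.frame(
        chain_a = NA_character_, ordinal_a = as.integer(m[[2]]),
        chain_b = NA_character_, ordinal_b = as.integer(m[[3]]),
        stringsAsFactors = FALSE))
    }
  } else {
    toks <- trimws(strsplit(txt, ",")[[1]])
    toks <- toks[nzchar(toks)]
    for (tk in toks) {
      if (grepl("^[A-Za-z]:[0-9]+\\|[A-Za-z]:[0-9]+$", tk)) {
        m <- regmatches(tk, regexec(
          "^([A-Za-z]):([0-9]+)\\|([A-Za-z]):([0-9]+)$", tk))[[1]]
        pairs <- rbind(pairs, data.frame(
          chain_a = m[[2]], ordinal_a = as.integer(m[[3]]),
          chain_b = m[[4]], ordinal_b = as.integer(m[[5]]),
          stringsAsFactors = FALSE))
      } else if (grepl("^C[0-9]+-C[0-9]+$", tk)) {
        m <- regmatches(tk, regexec("^C([0-9]+)-C([0-9]+)$", tk))[[1]]
        pairs <- rbind(pairs, data.frame(
          chain_a = NA_character_, ordinal_a = as.integer(m[[2]]),
          chain_b = NA_character_, ordinal_b = as.integer(m[[3]]),
          stringsAsFactors = FALSE))
      } else {
        stop("malformed notation token: '", tk, "'", call. = FALSE)
      }
    }
  }
  # normalize unordered pairs; chain-qualified pairs keep chain grouping
  same_chain <- is.na(pairs$chain_a) |
    (!is.na(pairs$chain_b) & pairs$chain_a == pairs$chain_b)
  flip <- same_chain & pairs$ordinal_a > pairs$ordinal_b
  tmp <- pairs$ordinal_a[flip]
  pairs$ordinal_a[flip] <- pairs$ordinal_b[flip]
  pairs$ordinal_b[flip] <- tmp
  key <- c(paste(pairs$chain_a, pairs$ordinal_a),
           paste(pairs$chain_b, pairs$ordinal_b))
  intra <- key[c(same_chain, same_chain)]
  if (anyDuplicated(intra)) {
    stop("ordinal used in more than one bond: ",
         intra[duplicated(intra)][[1]], call. = FALSE)
  }
  pairs <- pairs[order(pairs$ordinal_a, pairs$ordinal_b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

topology_bondset <- function(topology) {
  b <- intra_bonds(topology)
  if (nrow(b) == 0L) {
    return(data.frame(chain_a = character(), ordinal_a = integer(),
                      chain_b = character(), ordinal_b = integer(),
                      stringsAsFactors = FALSE))
  }
  lo <- pmin(b$ordinal_a, b$ordinal_b)
  hi <- pmax(b$ordinal_a, b$ordinal_b)
  o <- order(lo, hi)
  data.frame(chain_a = NA_character_, ordinal_a = lo[o],
             chain_b = NA_character_, ordinal_b = hi[o],
             stringsAsFactors = FALSE)
}

#' Consensus connectivity over a family of models
#'
#' @param topologies list of `disulfide_topology` (or `pdb_model`, which
#'   are run through [detect_bonds()] first) with equal cysteine ordinal
#'   counts.
#' @param threshold fraction of models a bond must appear in.
#' @param cutoff_angstrom forwarded to [detect_bonds()] for raw models.
#' @return list: `consensus` (ordinal pair data.frame), `support`
#'   (data.frame of every observed bond + support fraction), `n_models`.
#' @export
consensus_topology <- function(topologies, threshold = 0.8,
                               cutoff_angstrom = 3.0) {
  if (length(topologies) < 2L) stop("need >= 2 models", call. = FALSE)
  topologies <- lapply(topologies, function(t) {
    if (inherits(t, "pdb_model")) detect_bonds(t, cutoff_angstrom) else t
  })
  ncys <- vapply(topologies, function(t) nrow(t$sites), 1L)
  if (length(unique(ncys)) != 1L) {
    stop("models differ in cysteine count: ",
         paste(unique(ncys), collapse = ","), call. = FALSE)
  }
  keys <- lapply(topologies, function(t) {
    bs <- topology_bondset(t)
    paste0(bs$ordinal_a, "-", bs$ordinal_b)
  })
  all_keys <- sort(unique(unlist(keys)))
  support <- vapply(all_keys, function(k) {
    mean(vapply(keys, function(ks) k %in% ks, TRUE))
  }, 0)
  ords <- do.call(rbind, strsplit(all_keys, "-"))
  support_df <- data.frame(ordinal_a = as.integer(ords[, 1]),
                           ordinal_b = as.integer(ords[, 2]),
                           support = as.numeric(support),
                           stringsAsFactors = FALSE)
  support_df <- support_df[order(support_df$ordinal_a), , drop = FALSE]
  rownames(support_df) <- NULL
  cons <- support_df[support_df$support >= threshold,
                     c("ordinal_a", "ordinal_b"), drop = FALSE]
  rownames(cons) <- NULL
  list(consensus = cons, support = support_df,
       n_models = length(topologies))
}

#' Inter-chain disulfide scan for multimer models
#'
#' Lists inter-chain bonds separately and flags symmetric homodimer
#' bridges: a reciprocal flag is set when for a bond A:i|B:j the mirrored
#' bond A:j|B:i is also present (e.g. A:1|B:8 with A:8|B:1), and i == j
#' bonds (e.g. A:7|B:7) are symmetric by themselves.
#'
#' @param model multi-chain `pdb_model` (monomers yield an empty set).
#' @param cutoff_angstrom SG-SG cutoff.
#' @return list: `interchain` bond data.frame with `symmetric` flag,
#'   `free` data.frame, `notation` string, `symmetric_dimer` overall flag.
#' @export
dimer_bridge_scan <- function(model, cutoff_angstrom = 3.0) {
  topo <- detect_bonds(model, cutoff_angstrom)
  b <- interchain_bonds(topo)
  symmetric <- logical(nrow(b))
  if (nrow(b)) {
    key <- paste(b$chain_a, b$ordinal_a, b$chain_b, b$ordinal_b)
    mirror <- paste(b$chain_a, b$ordinal_b, b$chain_b, b$ordinal_a)
    symmetric <- (b$ordinal_a == b$ordinal_b) | (mirror %in% key)
  }
  b$symmetric <- symmetric
  list(interchain = b, free = topo$free,
       notation = notation_interchain(topo),
       symmetric_dimer = nrow(b) > 0L && all(symmetric))
}

#' Write a disulfide topology as TSV
#' @param topology `disulfide_topology`.
#' @param path output path.
#' @export
write_topology_tsv <- function(topology, path) {
  b <- topology$bonds
  b <- cbind(model_id = rep(topology$model_id, nrow(b)), b)
  write.table(b, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
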