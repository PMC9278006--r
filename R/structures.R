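# Structure representation, PDB I/O, and model/native residue correspondence.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")
WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

#' Two-partner protein complex structure
#'
#' Container for the atomic structure of a binary protein complex, split into
#' a receptor partner and a ligand partner (by docking-benchmark convention
#' the larger and smaller binding partner, respectively).  Only heavy atoms of
#' standard `ATOM` records are kept; coordinates are in Angstrom.
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer author
#'   numbering), `ins` (insertion code, `""` if none), `resid` (three-letter
#'   residue name), `elety` (atom name), `x`, `y`, `z`, `o` (occupancy), `b`
#'   (B-factor; carries pLDDT on the 0-100 scale in predictor-written files).
#' @param receptor_chains,ligand_chains character vectors of chain
#'   identifiers assigned to each partner.  Must be disjoint and jointly
#'   cover every chain present in `atoms`.
#' @param label free-text identifier (for example a PDB code).
#'
#' @return An object of class `complex_structure`: a list with elements
#'   `atoms` (as above, plus a `key` column `chain|resno|ins`),
#'   `receptor_chains`, `ligand_chains` and `label`.  Residues are ordered
#'   receptor chains first, then ligand chains, preserving file order within
#'   each chain.
#' @export
complex_structure <- function(atoms, receptor_chains, ligand_chains,
                              label = "") {
  receptor_chains <- as.character(receptor_chains)
  ligand_chains <- as.character(ligand_chains)
  if (length(intersect(receptor_chains, ligand_chains)) > 0L) {
    stop("receptor and ligand chain sets must be disjoint")
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  needed <- c("chain", "resno", "ins", "resid", "elety", "x", "y", "z",
              "o", "b")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(unique(atoms$chain),
                   c(receptor_chains, ligand_chains))
  if (length(extra) > 0L) {
    stop("chains not assigned to a partner: ", paste(extra, collapse = ", "))
  }
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite atomic coordinates")
  }
  # order: receptor chains first, then ligand chains, file order within chain
  chain_order <- c(receptor_chains, ligand_chains)
  ord <- order(match(atoms$chain, chain_order))
  atoms <- atoms[ord, , drop = FALSE]
  atoms$key <- residue_key(atoms$chain, atoms$resno, atoms$ins)
  rownames(atoms) <- NULL
  for (part in list(receptor_chains, ligand_chains)) {
    sub <- atoms[atoms$chain %in% part, , drop = FALSE]
    if (nrow(sub) == 0L || !any(sub$elety %in% BACKBONE_ATOMS)) {
      stop("each partner needs at least one residue with a backbone atom")
    }
  }
  structure(list(atoms = atoms,
                 receptor_chains = receptor_chains,
                 ligand_chains = ligand_chains,
                 label = label),
            class = "complex_structure")
}

residue_key <- function(chain, resno, ins) {
  ins <- ifelse(is.na(ins) | ins == " ", "", ins)
  paste(chain, resno, ins, sep = "|")
}

#' @export
print.complex_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("complex_structure", if (nzchar(x$label)) sQuote(x$label) else "",
      "\n  receptor:", paste(x$receptor_chains, collapse = ","),
      sprintf("(%d residues)", sum(rt$partner == "receptor")),
      "\n  ligand:  ", paste(x$ligand_chains, collapse = ","),
      sprintf("(%d residues)", sum(rt$partner == "ligand")),
      "\n  atoms:   ", nrow(x$atoms), "\n")
  invisible(x)
}

#' One row per residue, in structure order
#'
#' @param x a [complex_structure()].
#' @return data.frame with columns `key`, `chain`, `resno`, `ins`, `resid`,
#'   `partner` (`"receptor"` or `"ligand"`), ordered as the structure.
#' @export
residue_table <- function(x) {
  a <- x$atoms
  first <- !duplicated(a$key)
  out <- a[first, c("key", "chain", "resno", "ins", "resid"), drop = FALSE]
  out$partner <- ifelse(out$chain %in% x$receptor_chains,
                        "receptor", "ligand")
  rownames(out) <- NULL
  out
}

#' @rdname residue_table
#' @export
residue_keys <- function(x) residue_table(x)$key

# one-letter sequence of a chain, 'X' for residues without a standard parent;
# MSE and other common modified residues map to their parent via bio3d::aa321
chain_sequence <- function(x, chain) {
  rt <- residue_table(x)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  aa <- suppressWarnings(bio3d::aa321(rt$resid))
  aa[is.na(aa) | !aa %in% LETTERS] <- "X"
  list(seq = paste(aa, collapse = ""), keys = rt$key, aa = aa)
}

is_hydrogen_name <- function(elety) {
  grepl("^[0-9]*[HD]", trimws(elety)) & !trimws(elety) %in% BACKBONE_ATOMS
}

#' Read a two-partner complex from a PDB file
#'
#' Parses `ATOM` records (via \pkg{bio3d}), excluding `HETATM` records,
#' waters and hydrogens.  Alternate locations are resolved to the
#' highest-occupancy copy; ties keep the first record in file order.
#'
#' @param path PDB file path.
#' @param receptor_chains,ligand_chains chain identifiers of the two
#'   partners; every named chain must be present in the file.
#' @param label identifier stored on the result (default: file base name).
#' @return A [complex_structure()].
#' @export
read_pdb <- function(path, receptor_chains, ligand_chains,
                     label = sub("\\.pdb$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[!a$resid %in% WATER_RESIDUES, , drop = FALSE]
  a <- a[!is_hydrogen_name(a$elety), , drop = FALSE]
  wanted <- c(as.character(receptor_chains), as.character(ligand_chains))
  absent <- setdiff(wanted, unique(a$chain))
  if (length(absent) > 0L) {
    stop("chain(s) absent from ", path, ": ", paste(absent, collapse = ", "))
  }
  a <- a[a$chain %in% wanted, , drop = FALSE]
  if (nrow(a) == 0L) stop("zero residues after filtering in ", path)
  ins <- ifelse(is.na(a$insert), "", a$insert)
  occ <- ifelse(is.na(a$o), 1, a$o)
  df <- data.frame(chain = a$chain, resno = a$resno, ins = ins,
                   resid = a$resid, elety = trimws(a$elety),
                   x = a$x, y = a$y, z = a$z, o = occ, b = a$b,
                   stringsAsFactors = FALSE)
  # altloc resolution: highest occupancy per (residue, atom name), ties ->
  # first in file order (stable order of -o makes ties keep earlier rows)
  grp <- paste(df$chain, df$resno, df$ins, df$elety, sep = "|")
  pick <- order(-df$o)[!duplicated(grp[order(-df$o)])]
  df <- df[sort(pick), , drop = FALSE]
  complex_structure(df, receptor_chains, ligand_chains, label = label)
}

#' Write a complex structure as PDB ATOM records
#'
#' Coordinates are written at standard PDB precision (3 decimals).
#'
#' @param x a [complex_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  a <- x$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resid,
                   elety = a$elety, o = a$o, b = a$b)
  invisible(path)
}

# identity-scored global (Needleman-Wunsch, affine gaps) alignment of two
# one-letter sequences; returns aligned index pairs and fraction identity
align_sequences <- function(seq1, seq2) {
  if (identical(seq1, seq2)) {  # identity fast path
    n <- nchar(seq1)
    return(list(score = 2 * n, idx1 = seq_len(n), idx2 = seq_len(n),
                identical = rep(TRUE, n), identity = 1))
  }
  mat <- matrix(-1, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(mat) <- 2
  mat["X", ] <- -1; mat[, "X"] <- -1; mat["X", "X"] <- 0
  pa <- Biostrings::pairwiseAlignment(seq1, seq2,
                                      substitutionMatrix = mat,
                                      gapOpening = 10, gapExtension = 0.5,
                                      type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  i <- cumsum(p != "-")
  j <- cumsum(s != "-")
  both <- p != "-" & s != "-"
  idx1 <- i[both]; idx2 <- j[both]
  same <- p[both] == s[both]
  n_aln <- sum(both)
  list(score = Biostrings::score(pa),
       idx1 = idx1, idx2 = idx2, identical = same,
       identity = if (n_aln > 0) sum(same) / n_aln else 0)
}

# all injective assignments of the smaller chain set into the larger
chain_assignments <- function(model_chains, native_chains) {
  nm <- length(model_chains); nn <- length(native_chains)
  if (nm <= nn) {
    perms <- perms_of(seq_len(nn))
    unique(lapply(perms, function(p) {
      data.frame(model = model_chains, native = native_chains[p[seq_len(nm)]],
                 stringsAsFactors = FALSE)
    }))
  } else {
    perms <- perms_of(seq_len(nm))
    unique(lapply(perms, function(p) {
      data.frame(model = model_chains[p[seq_len(nn)]], native = native_chains,
                 stringsAsFactors = FALSE)
    }))
  }
}

perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Map residues between a model and a native complex
#'
#' For each partner, model chains are assigned to native chains by the
#' injective assignment maximizing the summed global alignment score
#' (identity scoring, affine gaps).  Aligned positions with identical amino
#' acids become residue pairs; mismatched or unaligned residues go to the
#' `model_only` / `native_only` sets.  Correspondence is purely
#' alignment-based, so author renumbering (for example the +200 chain-break
#' index shift used when feeding complexes to a single-chain predictor) does
#' not affect the mapping.
#'
#' @param model,native [complex_structure()] objects with the same partner
#'   layout (receptor and ligand).
#' @return An object of class `residue_mapping`: list with `pairs`
#'   (data.frame `model_key`, `native_key`, `partner`), `model_only`,
#'   `native_only` (character vectors of keys) and `chain_pairing`
#'   (data.frame `model_chain`, `native_chain`, `partner`, `identity`).
#' @export
map_residues <- function(model, native) {
  pairs <- list(); chain_rows <- list()
  model_only <- character(0); native_only <- character(0)
  for (partner in c("receptor", "ligand")) {
    mc <- if (partner == "receptor") model$receptor_chains else model$ligand_chains
    nc <- if (partner == "receptor") native$receptor_chains else native$ligand_chains
    mseqs <- lapply(mc, chain_sequence, x = model)
    nseqs <- lapply(nc, chain_sequence, x = native)
    names(mseqs) <- mc; names(nseqs) <- nc
    # score every chain pair once
    alns <- list()
    for (i in mc) for (j in nc) {
      alns[[paste(i, j)]] <- align_sequences(mseqs[[i]]$seq, nseqs[[j]]$seq)
    }
    best <- NULL; best_score <- -Inf
    for (asg in chain_assignments(mc, nc)) {
      sc <- sum(vapply(seq_len(nrow(asg)), function(k) {
        alns[[paste(asg$model[k], asg$native[k])]]$score
      }, numeric(1)))
      if (sc > best_score) { best_score <- sc; best <- asg }
    }
    paired_m <- character(0); paired_n <- character(0)
    for (k in seq_len(nrow(best))) {
      i <- best$model[k]; j <- best$native[k]
      al <- alns[[paste(i, j)]]
      if (al$identity < 0.30) {
        stop("chain correspondence failed for ", partner, " partner (",
             i, " vs ", j, ", identity ", sprintf("%.2f", al$identity), ")")
      }
      mk <- mseqs[[i]]$keys; nk <- nseqs[[j]]$keys
      ok <- al$identical
      pairs[[length(pairs) + 1L]] <- data.frame(
        model_key = mk[al$idx1[ok]], native_key = nk[al$idx2[ok]],
        partner = partner, stringsAsFactors = FALSE)
      paired_m <- c(paired_m, mk[al$idx1[ok]])
      paired_n <- c(paired_n, nk[al$idx2[ok]])
      chain_rows[[length(chain_rows) + 1L]] <- data.frame(
        model_chain = i, native_chain = j, partner = partner,
        identity = al$identity, stringsAsFactors = FALSE)
    }
    all_m <- unlist(lapply(mseqs, `[[`, "keys"))
    all_n <- unlist(lapply(nseqs, `[[`, "keys"))
    model_only <- c(model_only, setdiff(all_m, paired_m))
    native_only <- c(native_only, setdiff(all_n, paired_n))
  }
  pairs <- do.call(rbind, pairs)
  if (anyDuplicated(pairs$model_key) || anyDuplicated(pairs$native_key)) {
    stop("internal error: residue mapping is not one-to-one")
  }
  structure(list(pairs = pairs,
                 model_only = model_only,
                 native_only = native_only,
                 chain_pairing = do.call(rbind, chain_rows)),
            class = "residue_mapping")
}

#' @export
print.residue_mapping <- function(x, ...) {
  cat("residue_mapping:", nrow(x$pairs), "pairs,",
      length(x$model_only), "model-only,",
      length(x$native_only), "native-only\n")
  invisible(x)
}

#' Prune model and native to their shared residues and atoms
#'
#' Keeps exactly the residue pairs of `mapping` in both structures, ordered
#' consistently (native residue order), and intersects atoms by name within
#' each pair.  This mirrors the removal, before comparison, of residues that
#' are modeled but unresolved in the experimental structure.
#'
#' @param model,native [complex_structure()] objects.
#' @param mapping the [map_residues()] result for this pair.
#' @return list with elements `model` and `native`, both pruned.
#' @export
prune_to_common <- function(model, native, mapping) {
  pr <- mapping$pairs
  # order pairs by native structure residue order
  nat_order <- residue_keys(native)
  pr <- pr[order(match(pr$native_key, nat_order)), , drop = FALSE]
  n2m <- stats::setNames(pr$model_key, pr$native_key)
  na <- native$atoms[native$atoms$key %in% pr$native_key, , drop = FALSE]
  ma <- model$atoms[model$atoms$key %in% pr$model_key, , drop = FALSE]
  na <- na[order(match(na$key, pr$native_key)), , drop = FALSE]
  # per native atom, the matching model atom (same residue pair, same name)
  hit <- match(paste(n2m[na$key], na$elety), paste(ma$key, ma$elety))
  ok <- !is.na(hit)
  m_new <- ma[hit[ok], , drop = FALSE]
  n_new <- na[ok, , drop = FALSE]
  for (part in c("receptor", "ligand")) {
    mchains <- if (part == "receptor") model$receptor_chains else model$ligand_chains
    if (!any(m_new$chain %in% mchains)) {
      stop("no shared residues for the ", part, " partner after pruning")
    }
  }
  m_new$key <- NULL; n_new$key <- NULL
  list(model = complex_structure(m_new, model$receptor_chains,
                                 model$ligand_chains, label = model$label),
       native = complex_structure(n_new, native$receptor_chains,
                                  native$ligand_chains,
                                  label = native$label))
}
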