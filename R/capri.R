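# CAPRI metrics: fnat, I-RMSD, L-RMSD, accuracy classification.

CAPRI_CLASSES <- c("high", "medium", "acceptable", "incorrect")

coords_of <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

# squared distances between two coordinate sets (rows of 3-vectors)
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

#' Cross-interface residue contacts
#'
#' A contact is a receptor-residue/ligand-residue pair with any heavy-atom
#' distance at or below `cutoff`.
#'
#' @param complex a [complex_structure()].
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @return Object of class `contact_map`: list with `pairs` (data.frame
#'   `receptor_key`, `ligand_key`) and `cutoff`.
#' @export
residue_contacts <- function(complex, cutoff) {
  stopifnot(cutoff > 0)
  a <- complex$atoms
  rec <- a[a$chain %in% complex$receptor_chains, , drop = FALSE]
  lig <- a[a$chain %in% complex$ligand_chains, , drop = FALSE]
  d2 <- cross_dist2(coords_of(rec), coords_of(lig))
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  rkeys <- unique(rec$key); lkeys <- unique(lig$key)
  ri <- match(rec$key, rkeys)[hit[, 1]]
  li <- match(lig$key, lkeys)[hit[, 2]]
  uniq <- !duplicated(ri + (li - 1) * length(rkeys))
  pairs <- data.frame(receptor_key = rkeys[ri[uniq]],
                      ligand_key = lkeys[li[uniq]],
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, cutoff = cutoff), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map:", nrow(x$pairs), "residue pairs at",
      x$cutoff, "Angstrom\n")
  invisible(x)
}

contact_ids <- function(cm) {
  paste(cm$pairs$receptor_key, cm$pairs$ligand_key, sep = "&")
}

#' Fraction of native contacts reproduced by a model
#'
#' Native cross-interface residue contacts are enumerated at `cutoff`; the
#' model's contacts are translated to native residue identities through the
#' mapping, and the reproduced fraction is returned.  Non-native contacts in
#' the model do not penalize the score.
#'
#' @param model,native pruned [complex_structure()] objects (see
#'   [prune_to_common()]).
#' @param mapping the [map_residues()] result.
#' @param cutoff heavy-atom contact cutoff in Angstrom (CAPRI uses 5).
#' @return fraction in `[0, 1]`.
#' @export
fnat <- function(model, native, mapping, cutoff = 5) {
  nat <- residue_contacts(native, cutoff)
  if (nrow(nat$pairs) == 0L) stop("no native interface: zero contacts at ",
                                  cutoff, " Angstrom")
  mod <- residue_contacts(model, cutoff)
  m2n <- stats::setNames(mapping$pairs$native_key, mapping$pairs$model_key)
  mod_nat <- paste(m2n[mod$pairs$receptor_key],
                   m2n[mod$pairs$ligand_key], sep = "&")
  sum(contact_ids(nat) %in% mod_nat) / nrow(nat$pairs)
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation (determinant +1) and translation minimizing the
#' RMSD between `moving` (transformed) and `fixed`, by singular value
#' decomposition of the coordinate covariance.
#'
#' @param moving,fixed n x 3 coordinate matrices with matching rows
#'   (n >= 3).
#' @return list with `rotation` (3 x 3, applied as `x %*% rotation`),
#'   `translation` (length-3), and `rmsd` (Angstrom).
#' @export
kabsch_rmsd <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!all(dim(moving) == dim(fixed))) stop("point-count mismatch")
  if (nrow(moving) < 3L) stop("need at least 3 points")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  xm <- sweep(moving, 2, cm); xf <- sweep(fixed, 2, cf)
  h <- crossprod(xm, xf)
  sv <- svd(h)
  d <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- xm %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - xf)^2)))
  list(rotation = rot, translation = as.numeric(cf - cm %*% rot),
       rmsd = rmsd)
}

apply_transform <- function(x, tr) {
  sweep(as.matrix(x) %*% tr$rotation, 2, -tr$translation)
}

# matched backbone coordinates for mapped residue pairs (optionally a
# subset given by native keys); atoms intersected by name per pair
matched_backbone <- function(model, native, mapping, native_keys = NULL) {
  pr <- mapping$pairs
  if (!is.null(native_keys)) {
    pr <- pr[pr$native_key %in% native_keys, , drop = FALSE]
  }
  ma <- model$atoms[model$atoms$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  na <- native$atoms[native$atoms$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  m_id <- paste(ma$key, ma$elety); n_id <- paste(na$key, na$elety)
  n2m <- stats::setNames(pr$model_key, pr$native_key)
  nat_sub <- na[na$key %in% pr$native_key, , drop = FALSE]
  want_m <- paste(n2m[nat_sub$key], nat_sub$elety)
  hit <- match(want_m, m_id)
  ok <- !is.na(hit)
  list(model = coords_of(ma[hit[ok], , drop = FALSE]),
       native = coords_of(nat_sub[ok, , drop = FALSE]),
       n_native_backbone = nrow(nat_sub))
}

#' Interface RMSD
#'
#' The native interface is the set of residues (either partner) with any
#' heavy atom within `interface_cutoff` of the other partner, measured on
#' the native structure only.  Backbone atoms (`N`, `CA`, `C`, `O`) of those
#' residues are superposed (model onto native) and the minimized RMSD over
#' the same atoms is returned.
#'
#' @inheritParams fnat
#' @param interface_cutoff native-interface residue cutoff in Angstrom
#'   (CAPRI uses 10).
#' @return RMSD in Angstrom.
#' @export
irmsd <- function(model, native, mapping, interface_cutoff = 10) {
  cm <- residue_contacts(native, interface_cutoff)
  iface <- unique(c(cm$pairs$receptor_key, cm$pairs$ligand_key))
  mb <- matched_backbone(model, native, mapping, native_keys = iface)
  if (nrow(mb$native) < 3L) {
    stop("fewer than 3 backbone atoms in the native interface set")
  }
  kabsch_rmsd(mb$model, mb$native)$rmsd
}

#' Ligand RMSD
#'
#' Superposes the model onto the native by receptor backbone atoms, then
#' returns the backbone RMSD over ligand residues without further fitting.
#'
#' @inheritParams fnat
#' @return RMSD in Angstrom.
#' @export
lrmsd <- function(model, native, mapping) {
  rec_keys <- residue_table(native)
  rec_keys <- rec_keys$key[rec_keys$partner == "receptor"]
  lig_keys <- residue_table(native)
  lig_keys <- lig_keys$key[lig_keys$partner == "ligand"]
  rec <- matched_backbone(model, native, mapping, native_keys = rec_keys)
  if (nrow(rec$native) < 3L) stop("fewer than 3 receptor backbone atoms")
  tr <- kabsch_rmsd(rec$model, rec$native)
  lig <- matched_backbone(model, native, mapping, native_keys = lig_keys)
  fitted <- apply_transform(lig$model, tr)
  sqrt(mean(rowSums((fitted - lig$native)^2)))
}

#' CAPRI accuracy class from the three metrics
#'
#' The standard CAPRI decision table, evaluated top-down:
#' \itemize{
#'   \item high: fnat >= 0.5 and (L-RMSD <= 1.0 or I-RMSD <= 1.0)
#'   \item medium: fnat >= 0.3 and (L-RMSD <= 5.0 or I-RMSD <= 2.0)
#'   \item acceptable: fnat >= 0.1 and (L-RMSD <= 10.0 or I-RMSD <= 4.0)
#'   \item incorrect: otherwise
#' }
#'
#' @param fnat fraction of native contacts, in `[0, 1]`.  Vectorized.
#' @param lrmsd,irmsd ligand and interface RMSD in Angstrom (>= 0).
#' @return character vector of classes.
#' @export
classify_capri <- function(fnat, lrmsd, irmsd) {
  if (any(fnat < 0 | fnat > 1)) stop("fnat must be in [0, 1]")
  if (any(lrmsd < 0) || any(irmsd < 0)) stop("RMSD values must be >= 0")
  out <- rep("incorrect", length(fnat))
  out[fnat >= 0.1 & (lrmsd <= 10 | irmsd <= 4)] <- "acceptable"
  out[fnat >= 0.3 & (lrmsd <= 5 | irmsd <= 2)] <- "medium"
  out[fnat >= 0.5 & (lrmsd <= 1 | irmsd <= 1)] <- "high"
  out
}

#' Assess a model against the native complex with the CAPRI criteria
#'
#' Composes residue mapping, pruning to shared residues, fnat, I-RMSD,
#' L-RMSD and classification into a single result.
#'
#' @param model,native [complex_structure()] objects.
#' @param mapping optional precomputed [map_residues()] result; computed
#'   when `NULL`.
#' @param contact_cutoff fnat heavy-atom contact cutoff (Angstrom).
#' @param interface_cutoff native-interface residue cutoff for I-RMSD
#'   (Angstrom).
#' @return Object of class `capri_result`: list with `fnat`, `irmsd`,
#'   `lrmsd`, `capri_class`, `n_native_contacts`, `n_interface_residues`.
#' @export
assess <- function(model, native, mapping = NULL,
                   contact_cutoff = 5, interface_cutoff = 10) {
  if (is.null(mapping)) mapping <- map_residues(model, native)
  pruned <- prune_to_common(model, native, mapping)
  model <- pruned$model; native <- pruned$native
  nat_contacts <- residue_contacts(native, contact_cutoff)
  iface <- residue_contacts(native, interface_cutoff)
  n_iface <- length(unique(c(iface$pairs$receptor_key,
                             iface$pairs$ligand_key)))
  mb <- matched_backbone(model, native, mapping)
  if (nrow(mb$native) < 0.9 * mb$n_native_backbone) {
    warning("more than 10% of native backbone atoms have no model match")
  }
  f <- fnat(model, native, mapping, cutoff = contact_cutoff)
  ir <- irmsd(model, native, mapping, interface_cutoff = interface_cutoff)
  lr <- lrmsd(model, native, mapping)
  structure(list(fnat = f, irmsd = ir, lrmsd = lr,
                 capri_class = classify_capri(f, lr, ir),
                 n_native_contacts = nrow(nat_contacts$pairs),
                 n_interface_residues = n_iface),
            class = "capri_result")
}

#' @export
print.capri_result <- function(x, ...) {
  cat(sprintf(
    "capri_result: %s (fnat %.3f, I-RMSD %.3f, L-RMSD %.3f; %d native contacts)\n",
    x$capri_class, x$fnat, x$irmsd, x$lrmsd, x$n_native_contacts))
  invisible(x)
}
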