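# AlphaFold-style confidence data: loading, and interface-restricted metrics.

# sentinel values for models with no cross-interface contacts
NO_CONTACT_PLDDT <- 0
NO_CONTACT_PAE <- 35

#' Confidence data for one complex model
#'
#' @param plddt per-residue predicted LDDT on the 0-100 scale, ordered as
#'   the model's residues (receptor chains first).  Values on a 0-1 scale
#'   are rescaled to 0-100 with a warning.
#' @param pae optional square predicted-aligned-error matrix in Angstrom;
#'   entry `[i, j]` is the expected error in the position of residue `j`
#'   when the model is aligned on residue `i`.
#' @param ptm,iptm optional predicted TM-score scalars in `[0, 1]` (`iptm`
#'   is the interface-restricted variant emitted by multimer models).
#' @param model optional [complex_structure()]; when given, lengths are
#'   validated against its residue count and `plddt` is named by residue
#'   keys.
#' @param plddt_scale `"auto"` (default) rescales a vector that lies
#'   entirely in `[0, 1]` to 0-100 with a warning; `"0-100"` or `"0-1"`
#'   state the input scale explicitly.
#' @return Object of class `confidence_data`.
#' @export
confidence_data <- function(plddt, pae = NULL, ptm = NULL, iptm = NULL,
                            model = NULL,
                            plddt_scale = c("auto", "0-100", "0-1")) {
  plddt_scale <- match.arg(plddt_scale)
  plddt <- as.numeric(plddt)
  if (plddt_scale == "0-1" ||
      (plddt_scale == "auto" && all(plddt <= 1) && any(plddt > 0))) {
    if (plddt_scale == "auto") {
      warning("pLDDT appears to be on a 0-1 scale; rescaling to 0-100")
    }
    plddt <- plddt * 100
  }
  if (any(plddt < 0 | plddt > 100)) stop("pLDDT values outside [0, 100]")
  if (!is.null(pae)) {
    pae <- as.matrix(pae)
    if (nrow(pae) != ncol(pae)) stop("PAE matrix must be square")
    if (nrow(pae) != length(plddt)) {
      stop("PAE dimension does not match pLDDT length")
    }
    if (any(pae < 0)) stop("PAE entries must be >= 0")
  }
  for (s in list(ptm = ptm, iptm = iptm)) {
    if (!is.null(s) && (s < 0 || s > 1)) stop("pTM/ipTM must be in [0, 1]")
  }
  if (!is.null(model)) {
    keys <- residue_keys(model)
    if (length(plddt) != length(keys)) {
      stop("pLDDT length (", length(plddt),
           ") does not match model residue count (", length(keys), ")")
    }
    names(plddt) <- keys
    if (!is.null(pae)) dimnames(pae) <- list(keys, keys)
  }
  structure(list(plddt = plddt, pae = pae, ptm = ptm, iptm = iptm),
            class = "confidence_data")
}

#' @export
print.confidence_data <- function(x, ...) {
  cat("confidence_data:", length(x$plddt), "residues;",
      if (is.null(x$pae)) "no PAE;" else "PAE present;",
      "pTM", if (is.null(x$ptm)) "absent" else sprintf("%.3f", x$ptm), "\n")
  invisible(x)
}

#' Load confidence data from a predictor JSON file or from B-factors
#'
#' Accepts the JSON dialects written by common structure predictors: an
#' object carrying a per-residue pLDDT vector, a 2-D PAE array (nested
#' lists, or a flat list whose length is a perfect square), and pTM/ipTM
#' scalars.  Key names are configurable; the defaults cover `plddt` /
#' `predicted_lddt`, `pae` / `predicted_aligned_error`, `ptm` and `iptm`.
#' With `path = NULL` the per-residue mean B-factor of `model` is used as
#' pLDDT (the convention of predictor-written PDB files) and PAE/pTM are
#' absent.
#'
#' @param path JSON file path, or `NULL` to read pLDDT from B-factors.
#' @param model the [complex_structure()] the data belongs to.
#' @param keys named list giving the accepted JSON key names for each
#'   field.
#' @return A [confidence_data()] aligned to `model`'s residue order.
#' @export
load_confidence <- function(path, model,
                            keys = list(
                              plddt = c("plddt", "predicted_lddt", "lddt"),
                              pae = c("pae", "predicted_aligned_error",
                                      "distance"),
                              ptm = "ptm", iptm = "iptm")) {
  if (is.null(path)) {
    a <- model$atoms
    plddt <- vapply(split(a$b, factor(a$key, levels = unique(a$key))),
                    mean, numeric(1))
    return(confidence_data(plddt, model = model))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  # some dialects wrap the object in a length-1 list
  if (is.null(names(js)) && length(js) == 1L) js <- js[[1]]
  pick <- function(cands) {
    hit <- intersect(cands, names(js))
    if (length(hit) > 0L) js[[hit[[1]]]] else NULL
  }
  plddt <- pick(keys$plddt)
  if (is.null(plddt)) stop("no pLDDT field found in ", path)
  pae <- pick(keys$pae)
  if (!is.null(pae) && !is.matrix(pae)) {
    pae <- unlist(pae)
    n <- sqrt(length(pae))
    if (n != round(n)) stop("flat PAE list is not a perfect square")
    pae <- matrix(pae, nrow = n, byrow = TRUE)
  }
  ptm <- pick(keys$ptm); iptm <- pick(keys$iptm)
  confidence_data(plddt, pae = pae,
                  ptm = if (is.null(ptm)) NULL else as.numeric(ptm),
                  iptm = if (is.null(iptm)) NULL else as.numeric(iptm),
                  model = model)
}

#' Write confidence data as predictor-style JSON
#'
#' @param conf a [confidence_data()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_confidence <- function(conf, path) {
  out <- list(plddt = as.numeric(conf$plddt))
  if (!is.null(conf$pae)) out$pae <- matrix(as.numeric(conf$pae),
                                            nrow = nrow(conf$pae))
  if (!is.null(conf$ptm)) out$ptm <- conf$ptm
  if (!is.null(conf$iptm)) out$iptm <- conf$iptm
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Interface residues of a complex model
#'
#' Union of receptor-side and ligand-side residues participating in any
#' cross-partner heavy-atom contact at or below `cutoff`.
#'
#' @param model a [complex_structure()].
#' @param cutoff contact cutoff in Angstrom.  Values outside the 4-10
#'   range commonly explored for interface definitions trigger a warning.
#' @return character vector of residue keys (possibly empty).
#' @export
interface_residues <- function(model, cutoff = 4) {
  if (cutoff < 4 || cutoff > 10) {
    warning("interface cutoff ", cutoff, " Angstrom is outside the usual ",
            "4-10 range")
  }
  cm <- residue_contacts(model, cutoff)
  unique(c(cm$pairs$receptor_key, cm$pairs$ligand_key))
}

#' Interface pLDDT
#'
#' Arithmetic mean of per-residue pLDDT over the model's interface
#' residues.  Models with no cross-interface contacts at the cutoff are
#' assigned an interface pLDDT of 0.
#'
#' @param model a [complex_structure()].
#' @param conf a [confidence_data()] with `plddt` present.
#' @param cutoff interface contact cutoff in Angstrom (default 4).
#' @return score on the 0-100 scale.
#' @export
interface_plddt <- function(model, conf, cutoff = 4) {
  if (is.null(conf$plddt)) stop("pLDDT absent from confidence data")
  iface <- interface_residues(model, cutoff)
  if (length(iface) == 0L) return(NO_CONTACT_PLDDT)
  plddt <- conf$plddt
  if (is.null(names(plddt))) names(plddt) <- residue_keys(model)
  mean(plddt[iface])
}

#' Interface PAE
#'
#' Mean predicted aligned error over contacting cross-partner residue pairs,
#' symmetrized per pair as `(pae[i, j] + pae[j, i]) / 2` so the metric does
#' not depend on which partner is labeled receptor.  Models with no
#' contacting pairs are assigned an interface PAE of 35.
#'
#' @inheritParams interface_plddt
#' @return mean PAE in Angstrom.
#' @export
interface_pae <- function(model, conf, cutoff = 4) {
  if (is.null(conf$pae)) stop("PAE absent from confidence data")
  cm <- residue_contacts(model, cutoff)
  if (nrow(cm$pairs) == 0L) return(NO_CONTACT_PAE)
  pae <- conf$pae
  if (is.null(dimnames(pae)[[1]])) {
    keys <- residue_keys(model)
    dimnames(pae) <- list(keys, keys)
  }
  i <- cm$pairs$receptor_key; j <- cm$pairs$ligand_key
  mean((pae[cbind(i, j)] + pae[cbind(j, i)]) / 2)
}

#' Global pLDDT averages
#'
#' `average_plddt` is the mean over all residues; `average_resolved_plddt`
#' averages only residues paired to the native in `mapping` (residues
#' resolved in the experimental structure), discounting predicted regions
#' with no experimental counterpart.
#'
#' @param conf a [confidence_data()] whose `plddt` is named by residue keys
#'   (as produced by [load_confidence()]).
#' @return score on the 0-100 scale.
#' @export
average_plddt <- function(conf) {
  if (is.null(conf$plddt)) stop("pLDDT absent from confidence data")
  mean(conf$plddt)
}

#' @rdname average_plddt
#' @param mapping a [map_residues()] result; the model-side keys of its
#'   pairs define the resolved region.
#' @export
average_resolved_plddt <- function(conf, mapping) {
  if (is.null(conf$plddt)) stop("pLDDT absent from confidence data")
  if (is.null(names(conf$plddt))) {
    stop("plddt is not named by residue keys; load it with a model")
  }
  keys <- intersect(mapping$pairs$model_key, names(conf$plddt))
  if (length(keys) == 0L) stop("no resolved residues in mapping")
  mean(conf$plddt[keys])
}

#' Size and interface-fraction features of a complex
#'
#' @param model a [complex_structure()].
#' @param cutoff interface contact cutoff in Angstrom.
#' @return list with `total_residues`, `n_interface_residues` and
#'   `pct_interface` (percent of all residues at the interface).
#' @export
case_features <- function(model, cutoff = 4) {
  total <- length(residue_keys(model))
  n_iface <- length(interface_residues(model, cutoff))
  list(total_residues = total,
       n_interface_residues = n_iface,
       pct_interface = 100 * n_iface / total)
}
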