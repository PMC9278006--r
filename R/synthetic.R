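# Synthetic fixtures: ideal-helix toy complexes, rigid-body decoy series
# with analytically known ligand RMSD, and fabricated confidence maps.

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

# NeRF internal-coordinate atom placement: position d with |c-d| = bond,
# angle(b,c,d) = angle_deg and torsion(a,b,c,d) = torsion_deg
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ph <- torsion_deg * pi / 180
  d_local <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  as.numeric(c + cbind(bc, m, n) %*% d_local)
}

# ideal poly-alanine alpha-helix backbone (N, CA, C, O per residue) from
# literature-standard bond lengths/angles and (phi, psi, omega) =
# (-57, -47, 180) degrees; returns a (4 n) x 3 coordinate matrix
ideal_helix <- function(n_res, phi = -57, psi = -47, omega = 180) {
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329; b_co <- 1.231
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7; a_caco <- 120.8
  atoms <- matrix(NA_real_, nrow = 4 * n_res, ncol = 3)
  rownames(atoms) <- paste(rep(seq_len(n_res), each = 4),
                           rep(c("N", "CA", "C", "O"), n_res))
  idx <- function(i, name) 4 * (i - 1) + match(name, c("N", "CA", "C", "O"))
  atoms[idx(1, "N"), ] <- c(0, 0, 0)
  atoms[idx(1, "CA"), ] <- c(b_nca, 0, 0)
  th <- a_ncac * pi / 180
  atoms[idx(1, "C"), ] <- atoms[idx(1, "CA"), ] +
    b_cac * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_res)) {
    n_i <- atoms[idx(i, "N"), ]; ca_i <- atoms[idx(i, "CA"), ]
    c_i <- atoms[idx(i, "C"), ]
    atoms[idx(i, "O"), ] <- place_atom(n_i, ca_i, c_i,
                                       b_co, a_caco, psi + 180)
    if (i < n_res) {
      n_next <- place_atom(n_i, ca_i, c_i, b_cn, a_cacn, psi)
      ca_next <- place_atom(ca_i, c_i, n_next, b_nca, a_cnca, omega)
      c_next <- place_atom(c_i, n_next, ca_next, b_cac, a_ncac, phi)
      atoms[idx(i + 1, "N"), ] <- n_next
      atoms[idx(i + 1, "CA"), ] <- ca_next
      atoms[idx(i + 1, "C"), ] <- c_next
    }
  }
  atoms
}

# center a coordinate set and rotate its principal axis onto z
align_to_z <- function(xyz) {
  xyz <- sweep(xyz, 2, colMeans(xyz))
  v <- svd(xyz)$v[, 1]
  z <- c(0, 0, 1)
  axis <- c(v[2] * z[3] - v[3] * z[2],
            v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(axis^2))
  if (s < 1e-12) return(xyz)
  angle <- atan2(s, sum(v * z))
  xyz %*% t(rotation_matrix(axis / s, angle * 180 / pi))
}

# Rodrigues rotation matrix for a unit axis and angle in degrees
rotation_matrix <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

helix_atoms_df <- function(xyz, chain, resno_start = 1L, b = 90) {
  n_res <- nrow(xyz) / 4
  data.frame(chain = chain,
             resno = rep(resno_start + seq_len(n_res) - 1L, each = 4L),
             ins = "", resid = "ALA",
             elety = rep(c("N", "CA", "C", "O"), n_res),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             o = 1, b = b, stringsAsFactors = FALSE)
}

#' Build a toy two-chain helical complex
#'
#' Two idealized poly-alanine alpha-helices (backbone atoms N, CA, C, O
#' with literature-standard geometry) are placed side by side, axes
#' parallel, with the minimum inter-chain heavy-atom distance calibrated to
#' `gap`.  Chain A is the receptor and chain B the ligand.  A small
#' Gaussian coordinate jitter (`jitter_sd`) makes independently seeded toys
#' distinct; the result is deterministic for a fixed seed.
#'
#' @param n_res_receptor,n_res_ligand residue counts (>= 5).
#' @param gap target minimum inter-chain heavy-atom distance in Angstrom.
#' @param seed integer seed.
#' @param jitter_sd standard deviation of the per-coordinate jitter in
#'   Angstrom (applied before gap calibration).
#' @return A [complex_structure()] with chains `A` (receptor) and `B`
#'   (ligand).
#' @export
make_toy_complex <- function(n_res_receptor, n_res_ligand, gap = 4.5,
                             seed = 1, jitter_sd = 0.05) {
  stopifnot(n_res_receptor >= 5, n_res_ligand >= 5)
  with_seed(seed, {
    xa <- align_to_z(ideal_helix(n_res_receptor))
    xb <- align_to_z(ideal_helix(n_res_ligand))
    if (jitter_sd > 0) {
      xa <- xa + matrix(stats::rnorm(length(xa), 0, jitter_sd), ncol = 3)
      xb <- xb + matrix(stats::rnorm(length(xb), 0, jitter_sd), ncol = 3)
    }
    # calibrate the x-offset of chain B so min cross distance ~= gap
    min_dist_at <- function(off) {
      sqrt(min(cross_dist2(xa, sweep(xb, 2, c(off, 0, 0), "+"))))
    }
    lo <- 0; hi <- 60
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (min_dist_at(mid) < gap) lo <- mid else hi <- mid
    }
    off <- (lo + hi) / 2
    xb <- sweep(xb, 2, c(off, 0, 0), "+")
    atoms <- rbind(helix_atoms_df(xa, "A"),
                   helix_atoms_df(xb, "B"))
    complex_structure(atoms, receptor_chains = "A", ligand_chains = "B",
                      label = sprintf("toy_%d_%d_s%d", n_res_receptor,
                                      n_res_ligand, seed))
  })
}

#' Rigid-body perturbation specification
#'
#' @param rotation_angle rotation in degrees about `axis` through the
#'   ligand centroid.
#' @param axis length-3 rotation axis (need not be normalized).
#' @param translation length-3 translation vector in Angstrom, applied
#'   after the rotation.
#' @return Object of class `perturbation_spec`.  The zero spec leaves the
#'   model identical to the native.
#' @export
perturbation_spec <- function(rotation_angle = 0, axis = c(0, 0, 1),
                              translation = c(0, 0, 0)) {
  stopifnot(length(axis) == 3, length(translation) == 3)
  structure(list(rotation_angle = rotation_angle, axis = axis,
                 translation = translation),
            class = "perturbation_spec")
}

#' Apply a rigid-body perturbation to the ligand of a complex
#'
#' The receptor is untouched; the ligand is rotated about the spec's axis
#' through its own centroid, then translated.  For a pure translation the
#' ligand RMSD of the perturbed model equals the translation magnitude
#' exactly.
#'
#' @param native a [complex_structure()].
#' @param spec a [perturbation_spec()].
#' @return The perturbed [complex_structure()].
#' @export
perturb <- function(native, spec) {
  a <- native$atoms
  is_lig <- a$chain %in% native$ligand_chains
  xyz <- coords_of(a[is_lig, , drop = FALSE])
  cen <- colMeans(xyz)
  rot <- rotation_matrix(spec$axis, spec$rotation_angle)
  xyz <- sweep(sweep(xyz, 2, cen) %*% t(rot), 2, cen + spec$translation,
               "+")
  a$x[is_lig] <- xyz[, 1]; a$y[is_lig] <- xyz[, 2]; a$z[is_lig] <- xyz[, 3]
  a$key <- NULL
  complex_structure(a, native$receptor_chains, native$ligand_chains,
                    label = paste0(native$label, "_pert"))
}

#' Fabricate confidence data correlated with model accuracy
#'
#' Emulates the empirical association between interface confidence and
#' model accuracy: interface residues (any heavy atom within 8 Angstrom of
#' the other partner, in the model) receive pLDDT drawn around a value that
#' decreases with the model's true interface RMSD, non-interface residues
#' around a high-confidence baseline; cross-chain PAE entries are drawn
#' around a value increasing with interface RMSD (floored at 0.25
#' Angstrom) and within-chain entries around a small baseline.  Noise has
#' two components of equal standard deviation `noise_sd`: a model-level
#' offset shared by all residues (confidence errors are correlated within
#' a model) and independent per-residue noise.  PAE and pTM noise are
#' scaled proportionally to their ranges.  Noiseless output is a
#' deterministic function of `true_irmsd`.
#'
#' @param model the [complex_structure()] the data is fabricated for.
#' @param true_irmsd the model's interface RMSD in Angstrom.
#' @param noise_sd noise level in pLDDT units (>= 0).
#' @param seed integer seed.
#' @return A [confidence_data()].
#' @export
fabricate_confidence <- function(model, true_irmsd, noise_sd = 0,
                                 seed = 1) {
  stopifnot(noise_sd >= 0, true_irmsd >= 0)
  with_seed(seed, {
    keys <- residue_keys(model)
    n <- length(keys)
    iface <- interface_residues(model, cutoff = 8)
    mu_iface <- 97 / (1 + (true_irmsd / 3)^3)
    mu <- ifelse(keys %in% iface, mu_iface, 92)
    model_shift <- stats::rnorm(1, 0, noise_sd)
    plddt <- pmin(100, pmax(0, mu + model_shift +
                              stats::rnorm(n, 0, noise_sd)))
    rt <- residue_table(model)
    cross <- outer(rt$partner, rt$partner, "!=")
    mu_pae <- matrix(1.5, n, n)
    mu_pae[cross] <- min(32, 0.25 + 2.5 * true_irmsd)
    diag(mu_pae) <- 0.25
    pae <- pmax(mu_pae - model_shift * 0.35 +
                  matrix(stats::rnorm(n * n, 0, noise_sd * 0.35), n, n),
                0.25)
    diag(pae) <- pmin(diag(pae), 0.5)
    ptm <- min(0.95, max(0.05,
                         0.92 - 0.028 * true_irmsd +
                           model_shift / 100))
    confidence_data(plddt, pae = pae, ptm = ptm, model = model,
                    plddt_scale = "0-100")
  })
}

# candidate perturbations, mildest first, used to hit a target class;
# `sep` is the unit separation direction (receptor -> ligand centroid).
# The incorrect class has two phenotypes: a flipped binding orientation
# that keeps interface contacts, and a far translation with no contacts;
# `flip_first` picks which is tried first.
class_candidates <- function(target, sep, axis, flip_first = FALSE) {
  specs <- list()
  add <- function(s) specs[[length(specs) + 1L]] <<- s
  if (target == "high") {
    add(perturbation_spec())
  } else if (target == "incorrect") {
    flips <- list(perturbation_spec(rotation_angle = 180, axis = axis),
                  perturbation_spec(rotation_angle = 160, axis = axis))
    far <- list(perturbation_spec(translation = 30 * sep))
    for (s in if (flip_first) c(flips, far) else c(far, flips)) add(s)
  } else {
    ranges <- list(medium = list(ang = seq(5, 90, by = 5),
                                 tr = seq(0.8, 4, by = 0.4)),
                   acceptable = list(ang = seq(10, 150, by = 5),
                                     tr = seq(2, 9, by = 0.5)))
    rg <- ranges[[target]]
    for (k in seq_along(rg$ang)) {
      add(perturbation_spec(rotation_angle = rg$ang[k], axis = axis))
      if (k <= length(rg$tr)) {
        add(perturbation_spec(translation = rg$tr[k] * sep))
      }
    }
  }
  specs
}

separation_direction <- function(native) {
  a <- native$atoms
  rc <- colMeans(coords_of(a[a$chain %in% native$receptor_chains, ]))
  lc <- colMeans(coords_of(a[a$chain %in% native$ligand_chains, ]))
  d <- lc - rc
  d / sqrt(sum(d^2))
}

#' Generate a synthetic assessment benchmark
#'
#' For each case a toy native complex is built and a decoy series is
#' sampled to populate all four CAPRI classes: candidate rigid-body
#' perturbations of increasing severity are assessed and the first one
#' reaching each target class is kept (the assessment itself, not the
#' perturbation magnitude, is the arbiter of the class).  Fabricated
#' confidence data (see [fabricate_confidence()]) is attached to every
#' model and the per-model score table is assembled by running the CAPRI
#' and confidence metrics end to end.
#'
#' @param n_cases number of cases (>= 1).
#' @param models_per_case models per case (default 5: one per class plus
#'   one extra of a random class).
#' @param noise_sd confidence noise level in pLDDT units.
#' @param metric_cutoff interface cutoff (Angstrom) used when scoring the
#'   generated models with [interface_plddt()] and [interface_pae()];
#'   defaults to 8, matching the interface definition of
#'   [fabricate_confidence()].
#' @param seed integer seed; all randomness derives from it.
#' @return list with `cases` (per case: `native`, `models`, each model a
#'   list of `structure`, `spec`, `confidence`, `truth`) and `table` (a
#'   [score_table()] with columns `ptm`, `average_plddt`,
#'   `interface_plddt`, `interface_pae`; `interface_pae` flagged
#'   lower-is-better).
#' @export
generate_benchmark <- function(n_cases, models_per_case = 5, noise_sd = 0,
                               metric_cutoff = 8, seed = 1) {
  stopifnot(n_cases >= 1, models_per_case >= 4)
  with_seed(seed, {
    cases <- vector("list", n_cases)
    rows <- list()
    for (ci in seq_len(n_cases)) {
      case_id <- sprintf("case%03d", ci)
      n_rec <- sample(18:28, 1); n_lig <- sample(14:22, 1)
      case_seed <- sample.int(1e6, 1)
      native <- make_toy_complex(n_rec, n_lig, gap = 3.8,
                                 seed = case_seed)
      mapping <- map_residues(native, native)
      sep <- separation_direction(native)
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      targets <- c("high", "medium", "acceptable", "incorrect")
      if (models_per_case > 4) {
        targets <- c(targets,
                     sample(targets, models_per_case - 4, replace = TRUE))
      }
      models <- vector("list", length(targets))
      for (mi in seq_along(targets)) {
        flip_first <- stats::runif(1) < 0.5
        found <- NULL
        for (spec in class_candidates(targets[mi], sep, ax, flip_first)) {
          cand <- perturb(native, spec)
          res <- assess(cand, native, mapping = mapping)
          if (res$capri_class == targets[mi]) {
            found <- list(structure = cand, spec = spec, result = res)
            break
          }
        }
        if (is.null(found)) {  # keep the mildest candidate as fallback
          spec <- class_candidates(targets[mi], sep, ax, flip_first)[[1]]
          cand <- perturb(native, spec)
          found <- list(structure = cand, spec = spec,
                        result = assess(cand, native, mapping = mapping))
        }
        conf <- fabricate_confidence(found$structure,
                                     true_irmsd = found$result$irmsd,
                                     noise_sd = noise_sd,
                                     seed = sample.int(1e6, 1))
        pure_translation <- found$spec$rotation_angle == 0
        found$truth <- list(
          target_class = targets[mi],
          expected_lrmsd = if (pure_translation)
            sqrt(sum(found$spec$translation^2)) else NA_real_,
          assessed_class = found$result$capri_class)
        found$confidence <- conf
        models[[mi]] <- found
        rows[[length(rows) + 1L]] <- data.frame(
          case = case_id, rank = NA_integer_,
          capri_class = found$result$capri_class,
          ptm = conf$ptm,
          average_plddt = average_plddt(conf),
          interface_plddt = interface_plddt(found$structure, conf,
                                            cutoff = metric_cutoff),
          interface_pae = interface_pae(found$structure, conf,
                                        cutoff = metric_cutoff),
          fnat = found$result$fnat, irmsd = found$result$irmsd,
          lrmsd = found$result$lrmsd,
          stringsAsFactors = FALSE)
      }
      cases[[ci]] <- list(case = case_id, native = native,
                          models = models, seed = case_seed)
    }
    tab <- do.call(rbind, rows)
    # rank models within each case by pTM, best first
    tab <- do.call(rbind, lapply(split(tab, tab$case), function(d) {
      d <- d[order(-d$ptm), , drop = FALSE]
      d$rank <- seq_len(nrow(d))
      d
    }))
    rownames(tab) <- NULL
    list(cases = cases,
         table = score_table(tab,
                             directions = c(interface_pae = "lower",
                                            irmsd = "lower",
                                            lrmsd = "lower")))
  })
}

#' Write a generated benchmark to a fixtures directory
#'
#' Emits, per case, the native and model PDB files and per-model
#' confidence JSON, plus the assembled score table as TSV.
#'
#' @param bench a [generate_benchmark()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cs in bench$cases) {
    cdir <- file.path(dir, cs$case)
    dir.create(cdir, showWarnings = FALSE)
    write_pdb(cs$native, file.path(cdir, "native.pdb"))
    for (mi in seq_along(cs$models)) {
      m <- cs$models[[mi]]
      write_pdb(m$structure, file.path(cdir, sprintf("model_%d.pdb", mi)))
      write_confidence(m$confidence,
                       file.path(cdir, sprintf("model_%d.json", mi)))
    }
  }
  utils::write.table(bench$table, file.path(dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
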