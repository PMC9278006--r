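# fnat, Kabsch superposition, I-RMSD, L-RMSD, classification, assess.

random_points <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 5), ncol = 3)
}

random_rigid <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  list(rot = capriqa:::rotation_matrix(ax, runif(1, 0, 360)),
       trans = rnorm(3, sd = 10))
}

transform_structure <- function(st, rigid) {
  a <- st$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rigid$rot)
  xyz <- sweep(xyz, 2, rigid$trans, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  a$key <- NULL
  complex_structure(a, st$receptor_chains, st$ligand_chains,
                    label = st$label)
}

test_that("residue contacts respect the cutoff and match brute force", {
  df <- data.frame(chain = c("A", "B"), resno = 1, ins = "",
                   resid = "GLY", elety = "CA",
                   x = c(0, 4.9), y = 0, z = 0, o = 1, b = 50)
  st <- complex_structure(df, "A", "B")
  expect_equal(nrow(residue_contacts(st, 5)$pairs), 1)
  expect_equal(nrow(residue_contacts(st, 4)$pairs), 0)

  for (seed in 1:5) {
    toy <- make_toy_complex(12, 8, gap = 3.7, seed = seed, jitter_sd = 0.3)
    for (cutoff in c(4, 5, 8)) {
      cm <- residue_contacts(toy, cutoff)
      got <- sort(paste(cm$pairs$receptor_key, cm$pairs$ligand_key))
      expect_equal(got, brute_force_contacts(toy, cutoff))
    }
  }
})

test_that("fnat is 1 for self, 0 for separated, fractional in between", {
  toy <- make_toy_complex(20, 15, gap = 3.8, seed = 2)
  mp <- map_residues(toy, toy)
  pr <- prune_to_common(toy, toy, mp)
  expect_equal(fnat(pr$model, pr$native, mp), 1.0)

  far <- perturb(toy, perturbation_spec(translation = c(50, 0, 0)))
  prf <- prune_to_common(far, toy, mp)
  expect_equal(fnat(prf$model, prf$native, mp), 0.0)

  # reproduced fraction counts mapped native contacts only
  nat <- residue_contacts(toy, 5)
  part <- perturb(toy, perturbation_spec(rotation_angle = 25))
  f <- fnat(part, toy, mp)
  mod <- residue_contacts(part, 5)
  ids_nat <- paste(nat$pairs$receptor_key, nat$pairs$ligand_key)
  ids_mod <- paste(mod$pairs$receptor_key, mod$pairs$ligand_key)
  expect_equal(f, sum(ids_nat %in% ids_mod) / length(ids_nat))
})

test_that("fnat errors when the native has no interface", {
  toy <- make_toy_complex(8, 6, gap = 12, seed = 1)
  mp <- map_residues(toy, toy)
  expect_error(fnat(toy, toy, mp), "no native interface")
})

test_that("kabsch_rmsd recovers rigid transforms and matches the
           quaternion closed form", {
  p <- random_points(10, 1)
  expect_equal(kabsch_rmsd(p, p)$rmsd, 0, tolerance = 1e-12)

  rot90 <- capriqa:::rotation_matrix(c(0, 0, 1), 90)
  q <- sweep(p %*% t(rot90), 2, c(3, -2, 7), "+")
  fit <- kabsch_rmsd(p, q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  for (seed in 1:25) {
    a <- random_points(6, seed)
    b <- random_points(6, seed + 1000)
    expect_equal(kabsch_rmsd(a, b)$rmsd, quaternion_rmsd(a, b),
                 tolerance = 1e-9)
    # direction symmetry
    expect_equal(kabsch_rmsd(a, b)$rmsd, kabsch_rmsd(b, a)$rmsd,
                 tolerance = 1e-9)
  }
})

test_that("kabsch_rmsd validates its inputs", {
  expect_error(kabsch_rmsd(random_points(4, 1), random_points(5, 2)),
               "mismatch")
  expect_error(kabsch_rmsd(random_points(2, 1), random_points(2, 2)),
               "at least 3")
})

test_that("irmsd is zero for self and for globally transformed models", {
  toy <- make_toy_complex(18, 12, gap = 3.8, seed = 4)
  mp <- map_residues(toy, toy)
  expect_equal(irmsd(toy, toy, mp), 0, tolerance = 1e-9)
  moved <- transform_structure(toy, random_rigid(7))
  expect_equal(irmsd(moved, toy, mp), 0, tolerance = 1e-8)
})

test_that("irmsd of a ligand-shifted toy equals an independent
           superposition of the interface backbone", {
  toy <- make_toy_complex(18, 12, gap = 3.8, seed = 4)
  mp <- map_residues(toy, toy)
  model <- perturb(toy, perturbation_spec(translation = c(2, 0, 0)))
  got <- irmsd(model, toy, mp)

  # oracle: enumerate the native interface set and superpose via the
  # quaternion closed form
  cm <- residue_contacts(toy, 10)
  iface <- unique(c(cm$pairs$receptor_key, cm$pairs$ligand_key))
  bb <- c("N", "CA", "C", "O")
  nat <- toy$atoms[toy$atoms$key %in% iface & toy$atoms$elety %in% bb, ]
  mod <- model$atoms[model$atoms$key %in% iface &
                       model$atoms$elety %in% bb, ]
  expect_equal(got,
               quaternion_rmsd(as.matrix(mod[, c("x", "y", "z")]),
                               as.matrix(nat[, c("x", "y", "z")])),
               tolerance = 1e-6)
})

test_that("lrmsd equals the translation magnitude for pure translations
           and the direct displacement RMS for centroid rotations", {
  toy <- make_toy_complex(18, 12, gap = 3.8, seed = 9)
  mp <- map_residues(toy, toy)
  expect_equal(lrmsd(toy, toy, mp), 0, tolerance = 1e-9)

  shifted <- perturb(toy, perturbation_spec(translation = c(0, 3, 0)))
  expect_equal(lrmsd(shifted, toy, mp), 3.0, tolerance = 1e-9)

  # rotation about the ligand centroid: receptor superposition is the
  # identity, so L-RMSD equals the direct per-atom displacement RMS
  rot <- perturb(toy, perturbation_spec(rotation_angle = 30,
                                        axis = c(1, 2, 0.5)))
  bb <- c("N", "CA", "C", "O")
  nat_l <- toy$atoms[toy$atoms$chain == "B" & toy$atoms$elety %in% bb, ]
  mod_l <- rot$atoms[rot$atoms$chain == "B" & rot$atoms$elety %in% bb, ]
  direct <- sqrt(mean((nat_l$x - mod_l$x)^2 + (nat_l$y - mod_l$y)^2 +
                        (nat_l$z - mod_l$z)^2))
  expect_equal(lrmsd(rot, toy, mp), direct, tolerance = 1e-9)
})

test_that("classify_capri implements the decision table", {
  expect_equal(classify_capri(0.8, 0.5, 0.4), "high")
  expect_equal(classify_capri(0.35, 4.0, 1.8), "medium")
  expect_equal(classify_capri(0.05, 2.0, 1.0), "incorrect")
  expect_equal(classify_capri(0.15, 8.0, 5.0), "acceptable")
  # boundary: high threshold met exactly
  expect_equal(classify_capri(0.5, 1.0, 3.0), "high")
  expect_error(classify_capri(1.2, 1, 1), "fnat")
  expect_error(classify_capri(0.5, -1, 1), ">= 0")
})

test_that("assess composes the metrics and is invariant to global rigid
           motion of the model", {
  toy <- make_toy_complex(20, 14, gap = 3.8, seed = 6)
  mp <- map_residues(toy, toy)
  self <- assess(toy, toy, mapping = mp)
  expect_equal(self$fnat, 1.0)
  expect_equal(self$irmsd, 0, tolerance = 1e-9)
  expect_equal(self$lrmsd, 0, tolerance = 1e-9)
  expect_equal(self$capri_class, "high")

  far <- assess(perturb(toy, perturbation_spec(translation = c(25, 0, 0))),
                toy, mapping = mp)
  expect_equal(far$capri_class, "incorrect")
  expect_equal(far$fnat, 0)

  model <- perturb(toy, perturbation_spec(rotation_angle = 15))
  base <- assess(model, toy, mapping = mp)
  for (seed in 1:4) {
    moved <- transform_structure(model, random_rigid(seed))
    res <- assess(moved, toy, mapping = mp)
    expect_equal(res$fnat, base$fnat)
    expect_equal(res$irmsd, base$irmsd, tolerance = 1e-7)
    expect_equal(res$lrmsd, base$lrmsd, tolerance = 1e-7)
  }
})

test_that("assessed classes always agree with the decision table applied
           to the computed metrics", {
  toy <- make_toy_complex(16, 12, gap = 3.8, seed = 13)
  mp <- map_residues(toy, toy)
  set.seed(42)
  for (i in 1:12) {
    spec <- perturbation_spec(rotation_angle = runif(1, 0, 180),
                              axis = rnorm(3),
                              translation = rnorm(3, sd = runif(1, 0, 8)))
    res <- assess(perturb(toy, spec), toy, mapping = mp)
    expect_equal(res$capri_class,
                 classify_capri(res$fnat, res$lrmsd, res$irmsd))
  }
})
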