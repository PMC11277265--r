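# ITP emission/parsing and the special-case topology builders.

ht <- cgparam:::harmonic_term

random_topology <- function(seed) {
  set.seed(seed)
  n <- sample(3:12, 1)
  beads <- data.frame(index = seq_len(n),
                      type = sample(c("C1", "SC2", "TC5", "P1", "Q5n"), n,
                                    TRUE),
                      residue = "RND", name = paste0("B", seq_len(n)),
                      charge = round(sample(seq(-1, 1, 0.05), n, TRUE), 4),
                      mass = 72)
  bonds <- lapply(seq_len(n - 1), function(i)
    ht("bond", c(i, i + 1), round(runif(1, 0.2, 0.6), 6),
       round(runif(1, 100, 20000), 2), 1L))
  ncons <- sample(0:2, 1)
  cons <- if (n > 3 && ncons) lapply(seq_len(ncons), function(j)
    ht("constraint", c(1L, as.integer(2 + j)), round(runif(1, 0.2, 0.5), 6),
       NA_real_, 1L)) else list()
  angles <- if (n >= 3) lapply(seq_len(n - 2), function(i)
    ht("angle", c(i, i + 1, i + 2), round(runif(1, 60, 175), 6),
       round(runif(1, 10, 500), 2), 2L)) else list()
  imps <- if (n >= 4) list(ht("improper", c(1L, 2L, 3L, 4L),
                             round(runif(1, -20, 20), 6),
                             round(runif(1, 5, 200), 2), 2L)) else list()
  # avoid pairs duplicated as bond and constraint
  cons <- Filter(function(t) abs(diff(t$indices)) > 1, cons)
  cg_topology("RND", beads, bonds = bonds, constraints = cons,
              angles = angles, impropers = imps)
}

expect_topology_equal <- function(a, b) {
  expect_equal(a$molecule_name, b$molecule_name)
  expect_equal(a$nrexcl, b$nrexcl)
  expect_equal(a$beads$type, b$beads$type)
  expect_equal(a$beads$charge, b$beads$charge, tolerance = 1e-9)
  expect_equal(a$beads$mass, b$beads$mass, tolerance = 1e-9)
  for (sec in c("bonds", "constraints", "angles", "impropers")) {
    expect_length(b[[sec]], length(a[[sec]]))
    for (i in seq_along(a[[sec]])) {
      expect_equal(a[[sec]][[i]]$indices, b[[sec]][[i]]$indices)
      expect_equal(a[[sec]][[i]]$equilibrium, b[[sec]][[i]]$equilibrium,
                   tolerance = 1e-9)
      expect_equal(a[[sec]][[i]]$force_constant, b[[sec]][[i]]$force_constant,
                   tolerance = 1e-9)
    }
  }
}

test_that("write/read round-trips every shipped fixture topology", {
  for (nm in cofactor_mappings()) {
    top <- as_cg_topology(cofactor_mapping(nm))
    # round equilibria/k to the emitted precision so the identity is exact
    top$bonds <- lapply(top$bonds, function(t) {
      t$equilibrium <- round(t$equilibrium, 6)
      t$force_constant <- round(t$force_constant, 2); t })
    top$angles <- lapply(top$angles, function(t) {
      t$equilibrium <- round(t$equilibrium, 6)
      t$force_constant <- round(t$force_constant, 2); t })
    top$impropers <- lapply(top$impropers, function(t) {
      t$equilibrium <- round(t$equilibrium, 6)
      t$force_constant <- round(t$force_constant, 2); t })
    expect_topology_equal(top, read_itp(write_itp(top)))
  }
})

test_that("write/read round-trips randomized topologies and survives
           whitespace fuzz", {
  for (seed in 1:25) {
    top <- random_topology(seed)
    txt <- write_itp(top)
    expect_topology_equal(top, read_itp(txt))

    # random extra whitespace and comments must not change the parse
    set.seed(seed + 1000)
    fuzz <- vapply(txt, function(ln) {
      ln <- gsub(" ", strrep(" ", sample(1:4, 1)), ln)
      if (runif(1) < 0.3) ln <- paste0("   ", ln, "   ; noise")
      ln
    }, character(1), USE.NAMES = FALSE)
    expect_topology_equal(top, read_itp(fuzz))
  }
})

test_that("the parser rejects unknown sections, function codes and indices", {
  top <- random_topology(2)
  txt <- write_itp(top)
  expect_error(read_itp(c(txt, "[ pairs ]", "1 2 1")), "unknown section")

  bad <- sub("^(\\s*\\d+\\s+\\d+)\\s+1\\s", "\\1 9 ",
             grep("^\\s*\\d+\\s+\\d+\\s+1\\s", txt, value = TRUE)[1])
  txt2 <- txt
  txt2[which(txt2 == grep("^\\s*\\d+\\s+\\d+\\s+1\\s", txt, value = TRUE)[1])[1]] <- bad
  expect_error(read_itp(txt2), "unsupported function code")

  gap <- write_itp(random_topology(3))
  gap <- sub("^\\s*2 ", "   7 ", gap)   # break index contiguity in [atoms]
  expect_error(read_itp(gap), "non-contiguous|outside")
})

test_that("empty bonded sections are omitted for a 1-bead molecule", {
  beads <- data.frame(index = 1L, type = "TC3", residue = "ONE", name = "B1",
                      charge = 0, mass = 36)
  txt <- write_itp(cg_topology("ONE", beads))
  expect_false(any(grepl("\\[ bonds \\]", txt)))
  expect_false(any(grepl("\\[ angles \\]", txt)))
  expect_true(any(grepl("\\[ atoms \\]", txt)))
})

test_that("a bead pair duplicated as bond and constraint is refused", {
  beads <- data.frame(index = 1:2, type = "TC3", residue = "X",
                      name = c("B1", "B2"), charge = 0, mass = 36)
  expect_error(
    cg_topology("X", beads,
                bonds = list(ht("bond", c(1, 2), 0.3, 100, 1L)),
                constraints = list(ht("constraint", c(2, 1), 0.3, NA, 1L))),
    "duplicated")
})

make_cla_with_constraints <- function() {
  m <- cofactor_mapping("CLA")
  top <- as_cg_topology(m)
  stiff <- cgparam:::stiff_bond_flags(m)
  top$constraints <- lapply(top$bonds[stiff], function(t)
    ht("constraint", t$indices, t$equilibrium, NA_real_, 1L))
  top$bonds <- top$bonds[!stiff]
  top
}

test_that("pheophytin derivation follows the Mg-removal rule", {
  cla <- make_cla_with_constraints()
  ncons <- length(cla$constraints)
  expect_gt(ncons, 0)
  pho <- derive_pheophytin(cla)

  expect_equal(nrow(pho$beads), nrow(cla$beads) - 1L)  # 23 -> 22
  expect_equal(net_charge(pho), 0)
  expect_length(pho$constraints, 0L)
  # every converted constraint carries k = 50000 with unchanged equilibrium
  conv <- Filter(function(t) t$force_constant == 50000, pho$bonds)
  mg <- which(cla$beads$type == "TQ3p")
  kept_cons <- Filter(function(t) !mg %in% t$indices, cla$constraints)
  expect_length(conv, length(kept_cons))
  expect_equal(sort(vapply(conv, `[[`, numeric(1), "equilibrium")),
               sort(vapply(kept_cons, `[[`, numeric(1), "equilibrium")))
  # no dangling references, indices repacked
  expect_true(all(vapply(pho$bonds, function(t) all(t$indices <= 22), TRUE)))

  # charge-zeroing is idempotent: a second application changes nothing
  expect_error(derive_pheophytin(pho), "not a chlorophyll-like")
  pho2 <- pho; pho2$beads$charge <- 0
  expect_equal(pho2$beads, pho$beads)
})

test_that("the OEX builder emits 4 beads with all 6 pairwise bonds", {
  s <- 0.3 / (2 * sqrt(2))
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * s
  oex <- build_oex(tetra)
  expect_equal(nrow(oex$beads), 4L)
  expect_length(oex$bonds, choose(4, 2))
  expect_true(all(vapply(oex$bonds, `[[`, numeric(1), "force_constant") ==
                  10000))
  expect_equal(vapply(oex$bonds, `[[`, numeric(1), "equilibrium"),
               rep(0.3, 6), tolerance = 1e-9)
  expect_equal(net_charge(oex), 2)       # +0.5 e per bead by default
  expect_equal(net_charge(build_oex(tetra, charge_mode = "per_bead")), 8)
  expect_error(build_oex(tetra[1:3, ]), "4 bead")
})

test_that("restraint building measures distances and applies k defaults", {
  fr <- cg_frame(rbind(c(0, 0, 0), c(0, 0, 0.4), c(1, 0, 0), c(1, 0.25, 0)))
  rs <- build_restraints(fr, rbind(c(1, 2), c(3, 4)))
  expect_equal(rs$r0, c(0.4, 0.25), tolerance = 1e-12)
  expect_equal(rs$k, c(1000, 1000))

  # a batch of 14 Mg-protein pairs -> 14 restraints
  set.seed(2)
  big <- cg_frame(matrix(rnorm(28 * 3), ncol = 3))
  prs <- cbind(1:14, 15:28)
  expect_equal(nrow(build_restraints(big, prs)), 14L)

  # elastic-bond override k = 300 is recorded
  expect_equal(unique(build_restraints(big, prs, k = 300)$k), 300)

  expect_error(build_restraints(cg_frame(rbind(c(0, 0, 0), c(0, 0, 0))),
                                rbind(c(1, 2))), "coincident")
})
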