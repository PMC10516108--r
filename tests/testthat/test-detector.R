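test_that("hand-placed geometries trigger exactly the intended contact", {
  # two apolar carbons 4.0 A apart: hydrophobic only
  cx <- list(atoms = tibble::tibble(
    role = c("protein", "ligand"), element = c("C", "C"),
    x = c(0, 4), y = 0, z = 0, charge = 0,
    ring_id = NA_integer_, aromatic = FALSE))
  expect_equal(unname(detect_interactions(cx)["hydrophobic"]), 1L)
  expect_equal(sum(detect_interactions(cx)), 1L)
  # far apart: nothing
  cx$atoms$x[2] <- 20
  expect_equal(sum(detect_interactions(cx)), 0L)
  # carboxylate-ammonium style pair at 3.5 A: ionic plus the co-occurring
  # hydrogen bond (both N and O are polar and within the H-bond cutoff)
  cx2 <- list(atoms = tibble::tibble(
    role = c("protein", "ligand"), element = c("N", "O"),
    x = c(0, 3.5), y = 0, z = 0, charge = c(1, -1),
    ring_id = NA_integer_, aromatic = FALSE))
  p2 <- detect_interactions(cx2)
  expect_equal(unname(p2["ionic"]), 1L)
  expect_equal(unname(p2["hydrogen_bond"]), 1L)
  # missing annotation errors by name
  bad <- list(atoms = tibble::tibble(role = "protein", element = "C",
                                     x = 0, y = 0, z = 0))
  expect_error(detect_interactions(bad), "charge")
})

test_that("planted complexes close the loop for single interactions", {
  for (ty in INTERACTION_TYPES) {
    planted <- setNames(1L, ty)
    got <- detect_interactions(make_complex(planted))
    expect_identical(got, do.call(interaction_profile, as.list(planted)),
                     label = ty)
  }
  # empty plant gives an all-zero profile
  expect_equal(sum(detect_interactions(make_complex())), 0L)
})

test_that("multi-contact plants and their scores agree with expectations", {
  planted <- c(hydrogen_bond = 2L, ionic = 1L)
  got <- detect_interactions(make_complex(planted, seed = 4))
  expect_identical(got, do.call(interaction_profile, as.list(planted)))
  expect_equal(score_profile(got), 2 * 3.5 + 7.5)
  # random multi-type plants close the loop
  set.seed(12)
  for (i in 1:10) {
    counts <- setNames(rpois(9, 0.6), INTERACTION_TYPES)
    got <- detect_interactions(make_complex(counts, seed = i))
    expect_identical(got, do.call(interaction_profile, as.list(counts)))
  }
  expect_error(make_complex(c(ionic = -1)), ">= 0")
  expect_error(make_complex(c(nonsense = 1)), "unknown")
})

test_that("geometric criteria are configurable", {
  cx <- make_complex(c(hydrophobic = 1))
  strict <- interaction_criteria(hydrophobic_max = 3.0)
  expect_equal(sum(detect_interactions(cx, strict)), 0L)
})
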