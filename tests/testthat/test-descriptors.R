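make_sums <- function(total, per = NULL, role = "receptor",
                      state = "bound") {
  per <- per %||% c(H = total, Ar = 0, D = 0, Ac = 0, P = 0, N = 0, O = 0)
  structure(list(total = total,
                 per_category = per[pharm_categories()],
                 role = role, state = state), class = "category_sums")
}

test_that("descriptor_names: 80 names, stated order and nomenclature", {
  nm <- descriptor_names()
  expect_length(nm, 80)
  expect_equal(nm[1], "T_RU")
  expect_true("rel. H_L" %in% nm)
  expect_equal(sum(grepl("_RL$", nm)), 16)
  expect_equal(sum(grepl("_R$|_RU$|_RB$", nm)), 32)
  expect_equal(sum(grepl("_L$|_LU$|_LB$", nm)), 32)
  expect_false(anyDuplicated(nm) > 0)
  expect_identical(nm, descriptor_names())  # stable
})

test_that("identity case: non-contacting pose gives delta 0, rel 1", {
  ru <- make_sums(100, state = "unbound")
  rb <- make_sums(100, state = "bound")
  lu <- make_sums(40, role = "ligand", state = "unbound")
  lb <- make_sums(40, role = "ligand", state = "bound")
  v <- derive_descriptor_vector(rb, ru, lb, lu)
  expect_equal(unname(v[grepl("^delta", names(v))]), rep(0, 24))
  expect_equal(unname(v[grepl("^rel", names(v))]), rep(1, 24))
})

test_that("fully buried ligand: delta T_L = T_LU, rel. T_L = 0", {
  ru <- make_sums(1000, state = "unbound")
  rb <- make_sums(1000, state = "bound")
  lu <- make_sums(350, role = "ligand", state = "unbound")
  lb <- make_sums(0, role = "ligand", state = "bound")
  v <- derive_descriptor_vector(rb, ru, lb, lu)
  expect_equal(unname(v["delta T_L"]), 350)
  expect_equal(unname(v["rel. T_L"]), 0)
})

test_that("worked example reproduces the descriptor algebra by hand", {
  ru <- make_sums(1000, state = "unbound")
  rb <- make_sums(800, state = "bound")
  lu <- make_sums(400, role = "ligand", state = "unbound")
  lb <- make_sums(100, role = "ligand", state = "bound")
  v <- derive_descriptor_vector(rb, ru, lb, lu)
  expect_equal(unname(v["delta T_R"]), 200)
  expect_equal(unname(v["delta T_L"]), 300)
  expect_equal(unname(v["delta T_RL"]), 500)
  expect_equal(unname(v["rel. T_RL"]), 900 / 1400)
  expect_equal(unname(v["rel. T_R"]), 0.8)
  expect_equal(unname(v["rel. T_L"]), 0.25)
})

test_that("zero-denominator relatives are imputed to 1 and flagged", {
  per_u <- c(H = 50, Ar = 0, D = 0, Ac = 0, P = 0, N = 0, O = 0)
  per_b <- c(H = 30, Ar = 0, D = 0, Ac = 0, P = 0, N = 0, O = 0)
  ru <- make_sums(50, per_u, state = "unbound")
  rb <- make_sums(30, per_b, state = "bound")
  lu <- make_sums(50, per_u, role = "ligand", state = "unbound")
  lb <- make_sums(30, per_b, role = "ligand", state = "bound")
  v <- derive_descriptor_vector(rb, ru, lb, lu)
  expect_equal(unname(v["rel. P_R"]), 1)
  expect_equal(unname(v["rel. P_RL"]), 1)
  # 6 empty categories x 3 blocks
  expect_equal(attr(v, "n_rel_imputed"), 18L)
  expect_error(derive_descriptor_vector(make_sums(-1), ru, lb, lu),
               "negative")
})

test_that("additivity and partition closure on computed complexes", {
  for (d in c(0.3, 0.8)) {
    cpx <- make_pocket_complex(d, n_receptor_atoms = 120, seed = 2)
    v <- pose_descriptors(cpx, n_points = 240)
    expect_equal(unname(v["delta T_RL"]),
                 unname(v["delta T_R"] + v["delta T_L"]), tolerance = 1e-9)
    for (m in c("R", "L", "RL")) {
      cats <- pharm_categories()
      expect_equal(sum(v[paste0("delta ", cats, "_", m)]),
                   unname(v[paste0("delta T_", m)]), tolerance = 1e-6)
    }
    expect_true(all(v[grepl("^rel", names(v))] >= 0 &
                      v[grepl("^rel", names(v))] <= 1))
    expect_true(all(v[grepl("^delta", names(v))] >= 0))
    expect_lt(v["rel. T_L"], 1)  # contact pose buries ligand surface
  }
})

test_that("descriptor_table shape, labels, duplicates and burial trend", {
  empty <- descriptor_table(list())
  expect_equal(nrow(empty), 0)
  expect_true(all(descriptor_names() %in% names(empty)))

  depths <- c(0, 0.25, 0.5, 0.75, 1)
  poses <- lapply(depths, function(d)
    make_pocket_complex(d, n_receptor_atoms = 120, ligand_n_atoms = 6,
                        seed = 4))
  labels <- data.frame(
    compound_id = vapply(poses, function(p) p$ligand$compound_id, ""),
    label = c(0, 0, 1, 1, 1))
  tab <- descriptor_table(poses, labels, n_points = 240)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$label, labels$label)
  expect_true(all(diff(tab[["delta T_L"]]) > 0))

  expect_error(descriptor_table(c(poses, poses[1]), n_points = 240),
               "duplicate")
})

test_that("three poses of one compound keep the shared compound_id", {
  p1 <- make_pocket_complex(0.2, n_receptor_atoms = 100, seed = 1)
  poses <- lapply(1:3, function(k) {
    p <- p1
    p$ligand$compound_id <- "cmpdX"
    p$ligand$pose_id <- paste0("cmpdX_", k)
    p
  })
  tab <- descriptor_table(poses, n_points = 64)
  expect_equal(tab$compound_id, rep("cmpdX", 3))
})
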