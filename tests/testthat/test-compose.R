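test_that("annotations are stored, replaced, and vocabulary-checked", {
  seg <- make_segment("intermediate", "brachial", list(l = 0.1, r = 0.004))
  seg <- annotate(seg, "j_in.v", "flow", "brachial_inlet")
  expect_equal(nrow(seg$annotations), 1)
  seg <- annotate(seg, "j_in.v", "flow", "renamed_inlet")
  expect_equal(nrow(seg$annotations), 1)
  expect_equal(seg$annotations$entity_term, "renamed_inlet")
  seg <- annotate(seg, "t", "time", "t")
  expect_equal(nrow(seg$annotations), 2)
  expect_error(annotate(seg, "nosuch", "flow", "x"), "unknown variable")
  expect_error(annotate(seg, "j_in.v", "pressure", "x"), "unknown property_term")
})

test_that("exact overlaps are proposed; disjoint annotations yield only time", {
  a <- make_segment("intermediate", "a", list(l = 0.1, r = 0.01))
  b <- make_segment("intermediate", "b", list(l = 0.08, r = 0.007))
  a <- annotate(a, "vx1", "flow", "brachial_inlet")
  b <- annotate(b, "j_in.v", "flow", "brachial_inlet")
  sugg <- suggest_mappings(a, b)
  exact <- sugg[sugg$score == "exact" & sugg$property != "time", ]
  expect_equal(nrow(exact), 1)
  expect_equal(exact$source_var, "vx1")
  expect_equal(exact$target_var, "j_in.v")
  expect_equal(exact$port_side, "a")
  # time is always proposed
  expect_true(any(sugg$property == "time"))

  b2 <- make_segment("intermediate", "b2", list(l = 0.08, r = 0.007))
  b2 <- annotate(b2, "j_in.v", "flow", "femoral_inlet")
  s2 <- suggest_mappings(a, b2, partial = FALSE)
  expect_equal(nrow(s2[s2$property != "time", ]), 0)
})

test_that("a flow source placeholder maps onto an upstream waveform output", {
  # a ventricle stand-in whose ejection flow is the one-junction common flow
  lv <- bg_module("lv",
    components = dplyr::bind_rows(
      bg_component("Sf_lv", "Sf", param_ref = "lv_wave"),
      bg_component("R_valve", "R", 1e4)
    ),
    junctions = bg_junction("j1", "one"),
    bonds = dplyr::bind_rows(bg_bond("b1", "Sf_lv", "j1"),
                             bg_bond("b2", "j1", "R_valve"))
  )
  lv <- annotate(lv, "j1.v", "flow", "cardiac_output")
  aorta <- make_segment("initial", "aorta", list(l = 0.1, r = 0.01))
  aorta <- annotate(aorta, "Sf", "flow", "cardiac_output")

  sugg <- suggest_mappings(lv, aorta, partial = FALSE)
  src <- sugg[sugg$port_role == "source" & !is.na(sugg$port_side), ]
  expect_equal(nrow(src), 1)
  expect_equal(src$port_side, "b")

  m <- merge_modules(lv, aorta, src, name = "heart_aorta")
  sf <- m$components[m$components$id == "aorta.Sf", ]
  expect_equal(sf$param_ref, "lv.j1.v")
  sys <- assemble_ode(m)
  # the aortic inflow now follows the ventricular flow: supplying lv_wave
  # drives both sides
  rhs <- evaluate_rhs(sys, setNames(numeric(nrow(sys$states)), sys$states$id),
                      list(lv_wave = 2e-4))
  expect_equal(rhs[["aorta.C_a.q"]], 2e-4, tolerance = 1e-12)
})

test_that("merging couples both directions from a single accepted mapping", {
  up <- make_segment("initial", "up", list(l = 0.1, r = 0.01))
  dn <- make_segment("intermediate", "dn", list(l = 0.08, r = 0.007))
  up <- annotate(up, "vx1", "flow", "edge")
  dn <- annotate(dn, "j_in.v", "flow", "edge")
  sugg <- suggest_mappings(up, dn, partial = FALSE)
  acc <- sugg[sugg$property == "flow", ]
  m <- merge_modules(up, dn, acc, name = "pair")

  # upstream outlet flow sum gains -v of the downstream inlet junction
  bal_up <- junction_balance(m, "up.j_out")
  bt <- setNames(bal_up$sum_terms$coef, bal_up$sum_terms$term)
  expect_equal(bt[["dn.j_in.v"]], -1)

  # downstream inlet potential sum gains +u of the upstream outlet junction
  bal_dn <- junction_balance(m, "dn.j_in")
  bt2 <- setNames(bal_dn$sum_terms$coef, bal_dn$sum_terms$term)
  expect_equal(bt2[["up.j_out.u"]], 1)

  # both ports of the pair are now bound
  expect_equal(sum(!is.na(m$ports$binding)), 2)
  expect_equal(m$ports$binding[m$ports$id == "dn.u_x"], "up.j_out.u")
})

test_that("the coupled pair reproduces the shared-node flow bookkeeping", {
  up <- make_segment("initial", "up", list(l = 0.1, r = 0.01))
  dn <- make_segment("terminal", "dn", list(l = 0.05, r = 0.005))
  up <- annotate(up, "vx1", "flow", "edge")
  dn <- annotate(dn, "j_in.v", "flow", "edge")
  sugg <- suggest_mappings(up, dn, partial = FALSE)
  m <- merge_modules(up, dn, sugg[sugg$property == "flow", ], name = "pair")
  sys <- assemble_ode(m)
  # the upstream outlet wall branch integrates (own inflow - downstream draw):
  # dq_b/dt = v_up - v_dn, the composed form of v* = -v_A - v_B at the seam
  row <- sys$A["up.C_b.q", ]
  expect_equal(row[["up.I.v"]], 1)
  expect_equal(row[["dn.I.v"]], -1)
})

test_that("merge with nothing accepted is a disjoint union sharing time", {
  a <- make_segment("intermediate", "a", list(l = 0.1, r = 0.01))
  b <- make_segment("intermediate", "b", list(l = 0.08, r = 0.007))
  m <- merge_modules(a, b, name = "du")
  expect_equal(nrow(m$components), nrow(a$components) + nrow(b$components))
  expect_true(all(is.na(m$ports$binding)))
  sys <- assemble_ode(m)
  expect_equal(nrow(sys$states), 4)
  # block structure: no cross coupling
  expect_equal(sys$A[grep("^a\\.", rownames(sys$A)),
                     grep("^b\\.", colnames(sys$A))],
               matrix(0, 2, 2, dimnames = list(grep("^a\\.", rownames(sys$A), value = TRUE),
                                               grep("^b\\.", colnames(sys$A), value = TRUE))))
})

test_that("merging a module with itself needs a rename", {
  a <- make_segment("intermediate", "a", list(l = 0.1, r = 0.01))
  expect_error(merge_modules(a, a, name = "x"), "duplicate namespace")
  expect_error(merge_modules(a, clone_module(a, "L_"), name = "x"), NA)
})

test_that("clone renames everything and preserves structure", {
  limb <- small_limb()
  cl <- clone_module(limb, "R_", function(e) sub("^inlet_", "inlet_R_", e))
  expect_equal(nrow(cl$components), nrow(limb$components))
  expect_length(intersect(cl$components$id, limb$components$id), 0)
  expect_true(all(startsWith(cl$junctions$id, "R_")))
  expect_true(all(grepl("^inlet_R_|^t$", cl$annotations$entity_term)))
  expect_length(validate_module(cl), 0)
  expect_error(clone_module(limb, ""), "prefix")
})

test_that("cloned modules simulate identically to their original", {
  limb <- small_limb()
  cl <- clone_module(limb, "R_")
  w <- beat_waveform()
  s1 <- simulate_ode(assemble_ode(limb), inputs = list(cardiac_inflow = w),
                     t_end = 1)
  s2 <- simulate_ode(assemble_ode(cl), inputs = list(cardiac_inflow = w),
                     t_end = 1)
  expect_identical(unname(as.matrix(s1)), unname(as.matrix(s2)))
})

test_that("lump executes n-1 merges and leaves only unresolved ports", {
  toy <- toy_tree()
  comp <- lump(toy$plan, toy$modules)
  expect_equal(comp$meta$n_merges, 4)
  expect_equal(plan_size(toy$plan)$n_merges, 4)
  # each of the 4 accepted couplings consumes one flow and one potential port
  total_ports <- sum(vapply(toy$modules, function(m) nrow(m$ports), numeric(1)))
  expect_equal(sum(is.na(comp$ports$binding)), total_ports - 2 * 4)
  # single-leaf plan is the identity
  one <- lump(list(name = "solo", children = list(list(module = "root"))),
              toy$modules)
  expect_equal(nrow(one$components), nrow(toy$modules$root$components))
})

test_that("ambiguous exact mappings are rejected, not guessed", {
  a <- make_segment("initial", "a", list(l = 0.1, r = 0.01))
  b <- make_segment("terminal", "b", list(l = 0.05, r = 0.005))
  b2 <- make_segment("terminal", "c", list(l = 0.05, r = 0.005))
  a <- annotate(a, "vx1", "flow", "edge")
  b <- annotate(b, "j_in.v", "flow", "edge")
  b2 <- annotate(b2, "j_in.v", "flow", "edge")
  du <- merge_modules(b, b2, name = "beds")
  plan <- list(name = "x", children = list(list(module = "a"), list(module = "du")))
  expect_error(lump(plan, list(a = a, du = du)), "ambiguous")
})

test_that("composition is associative up to renaming", {
  geom <- tibble::tibble(
    segment_id = c("a", "b", "c"),
    kind = c("initial", "intermediate", "terminal"),
    length_m = c(0.1, 0.08, 0.05),
    radius_m = c(0.01, 0.007, 0.005),
    parent_id = c(NA, "a", "b")
  )
  sm <- segment_modules(geom)
  left <- lump(list(name = "n", children = list(
    list(name = "ab", children = list(list(module = "a"), list(module = "b"))),
    list(module = "c")
  )), sm$modules)
  right <- lump(list(name = "n", children = list(
    list(module = "a"),
    list(name = "bc", children = list(list(module = "b"), list(module = "c")))
  )), sm$modules)
  sys_l <- assemble_ode(left)
  sys_r <- assemble_ode(right)
  mono <- assemble_ode(monolithic_tree(geom))
  expect_lt(rhs_max_rel_diff(sys_l, mono, n_points = 25, seed = 3), 1e-12)
  expect_lt(rhs_max_rel_diff(sys_r, mono, n_points = 25, seed = 3), 1e-12)
})
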