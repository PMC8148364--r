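test_that("a minimal single-component module builds and validates", {
  m <- bg_module("tiny",
    components = bg_component("C", "C", 1e-9),
    junctions = bg_junction("j0", "zero"),
    bonds = bg_bond("b1", "j0", "C"),
    ports = bg_port("vx1", "j0", "flow")
  )
  expect_s3_class(m, "bg_module")
  expect_length(validate_module(m), 0)
})

test_that("referential and structural errors are rejected at build time", {
  expect_error(
    bg_module("bad",
      components = bg_component("C", "C", 1e-9),
      junctions = bg_junction("j0", "zero"),
      bonds = bg_bond("b1", "j0", "nosuch")
    ),
    "dangling endpoint"
  )
  expect_error(
    bg_module("bad",
      components = bg_component("C", "C", 1e-9),
      junctions = bg_junction("j1", "one"),
      bonds = bg_bond("b1", "j1", "C"),
      ports = bg_port("vx1", "j1", "flow")
    ),
    "port/junction mismatch"
  )
})

test_that("validate_module returns violations without raising", {
  m <- bg_module("ok",
    components = dplyr::bind_rows(bg_component("R", "R", 10),
                                  bg_component("Se", "Se", 0)),
    junctions = bg_junction("j1", "one"),
    bonds = dplyr::bind_rows(bg_bond("b1", "j1", "R"), bg_bond("b2", "j1", "Se"))
  )
  expect_identical(validate_module(m), character(0))

  # component with two bonds
  m2 <- m
  m2$bonds <- dplyr::bind_rows(m2$bonds, bg_bond("b3", "j1", "R"))
  expect_true(any(grepl("component R: multiple bonds", validate_module(m2))))

  # nonpositive parameter
  m3 <- m
  m3$components$param[m3$components$id == "R"] <- -1
  expect_true(any(grepl("component R: nonpositive parameter", validate_module(m3))))

  # duplicate ids
  m4 <- m
  m4$junctions <- dplyr::bind_rows(m4$junctions, bg_junction("j1", "zero"))
  expect_true(any(grepl("duplicate id", validate_module(m4))))
})

balance_terms <- function(bal) {
  setNames(bal$sum_terms$coef[bal$sum_terms$role != "port_unbound"],
           bal$sum_terms$term[bal$sum_terms$role != "port_unbound"])
}

test_that("zero-junction balance: equal potentials, signed flow sum, port at 0", {
  m <- bg_module("jz",
    components = dplyr::bind_rows(
      bg_component("Sf", "Sf", 1e-5),
      bg_component("R1", "R", 1), bg_component("R2", "R", 2)
    ),
    junctions = dplyr::bind_rows(bg_junction("j0", "zero"),
                                 bg_junction("ja", "one"), bg_junction("jb", "one")),
    bonds = dplyr::bind_rows(
      bg_bond("b1", "Sf", "j0"),     # inbound
      bg_bond("b2", "j0", "ja"),     # outbound
      bg_bond("b3", "j0", "jb"),     # outbound
      bg_bond("br1", "ja", "R1"), bg_bond("br2", "jb", "R2")
    ),
    ports = bg_port("vx1", "j0", "flow")
  )
  bal <- junction_balance(m, "j0")
  expect_equal(bal$kind, "zero")
  expect_setequal(bal$equalities$lhs, c("b1.u", "b2.u", "b3.u"))
  expect_true(all(bal$equalities$rhs == "j0.u"))
  tm <- balance_terms(bal)
  expect_equal(tm[["b1.v"]], 1)
  expect_equal(tm[["b2.v"]], -1)
  expect_equal(tm[["b3.v"]], -1)
  expect_true("port_unbound" %in% bal$sum_terms$role)

  # binding the port adds the external flow with a minus sign
  m$ports$binding[1] <- "ext.j.v"
  tm2 <- balance_terms(junction_balance(m, "j0"))
  expect_equal(tm2[["ext.j.v"]], -1)
})

test_that("one-junction with a through pair is a pass-through", {
  m <- bg_module("jo",
    components = dplyr::bind_rows(bg_component("Sf", "Sf", 1),
                                  bg_component("Se", "Se", 0)),
    junctions = bg_junction("j1", "one"),
    bonds = dplyr::bind_rows(bg_bond("b1", "Sf", "j1"), bg_bond("b2", "j1", "Se"))
  )
  bal <- junction_balance(m, "j1")
  expect_setequal(bal$equalities$lhs, c("b1.v", "b2.v"))
  tm <- balance_terms(bal)
  expect_equal(tm[["b1.u"]], 1)
  expect_equal(tm[["b2.u"]], -1)
})

test_that("an isolated junction is an error", {
  m <- bg_module("iso",
    components = bg_component("C", "C", 1),
    junctions = dplyr::bind_rows(bg_junction("j0", "zero"),
                                 bg_junction("j1", "one")),
    bonds = dplyr::bind_rows(bg_bond("b1", "j0", "C"), bg_bond("b2", "j0", "j1"))
  )
  m$bonds <- m$bonds[m$bonds$id != "b2", ]  # leave j1 dangling
  expect_error(junction_balance(m, "j1"), "isolated junction")
})

test_that("junction balance is invariant under bond reordering", {
  seg <- make_segment("intermediate", "s", list(l = 0.1, r = 0.01))
  perm <- seg
  withr::with_seed(7, {
    perm$bonds <- perm$bonds[sample(nrow(perm$bonds)), ]
  })
  for (j in seg$junctions$id) {
    a <- junction_balance(seg, j)
    b <- junction_balance(perm, j)
    expect_equal(dplyr::arrange(a$equalities, lhs), dplyr::arrange(b$equalities, lhs))
    ta <- balance_terms(a); tb <- balance_terms(b)
    expect_equal(ta[sort(names(ta))], tb[sort(names(tb))])
  }
})

test_that("signed power residual vanishes once balance equations hold", {
  # property: draw random co-variable values consistent with the junction
  # equations of a template, then sum u*v signed by orientation
  seg <- make_segment("terminal", "s", list(l = 0.05, r = 0.005))
  withr::with_seed(11, {
    for (rep in 1:20) {
      for (j in seg$junctions$id) {
        bal <- junction_balance(seg, j)
        inc <- seg$bonds[seg$bonds$tail == j | seg$bonds$head == j, ]
        sigma <- ifelse(inc$head == j, 1, -1)
        n <- nrow(inc)
        if (bal$kind == "zero") {
          u <- rep(rnorm(1), n)                       # common potential
          v <- rnorm(n)
          v[n] <- sigma[n] * (-sum(sigma[-n] * v[-n])) # close the flow sum
        } else {
          v <- rep(rnorm(1), n)
          u <- rnorm(n)
          u[n] <- sigma[n] * (-sum(sigma[-n] * u[-n]))
        }
        expect_lt(abs(sum(sigma * u * v)), 1e-12 * max(1, max(abs(u * v))))
      }
    }
  })
})

test_that("unbound ports leave the equations identical to a port-free build", {
  seg <- make_segment("initial", "s", list(l = 0.1, r = 0.01))
  bare <- seg
  bare$ports <- bare$ports[0, ]
  sys_p <- assemble_ode(seg)
  sys_b <- assemble_ode(bare)
  expect_equal(sys_p$A, sys_b$A)
  expect_equal(sys_p$B, sys_b$B)
  expect_equal(sys_p$b0, sys_b$b0)
  expect_equal(sys_p$outputs, sys_b$outputs)
  expect_gt(length(sys_p$port_warnings), 0)
})
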