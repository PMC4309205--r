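toggle_setup <- function() {
  lts <- build_lts(toggle_model())
  list(lts = lts,
       patterns = list(PA = c(A = 1L, B = 0L), PB = c(A = 0L, B = 1L)),
       environments = list(e0 = c(I = 0L), e1 = c(I = 1L)))
}

test_that("the labeled transition system carries input valuations on edges", {
  lts <- build_lts(toggle_model())
  expect_identical(nrow(lts$states), 4L)
  key <- paste(state_label(lts$states[lts$edges$from, , drop = FALSE]),
               state_label(lts$states[lts$edges$to, , drop = FALSE]),
               sep = ">")
  lab <- setNames(split(lts$labels, row(lts$labels)), key)
  # valuation order: I=0 then I=1
  expect_identical(lab[["10>00"]], c(TRUE, FALSE))
  expect_identical(lab[["00>10"]], c(FALSE, TRUE))
  expect_identical(lab[["00>01"]], c(TRUE, TRUE))

  # a model with no inputs has a single always-true label column
  nolts <- build_lts(negative_circuit_model())
  expect_identical(ncol(nolts$labels), 1L)
  expect_true(all(nolts$labels))

  # STEP: the ladder goes up under J=1 and down under J=0
  slts <- build_lts(step_model())
  skey <- paste(slts$states[slts$edges$from, 1], slts$states[slts$edges$to, 1],
                sep = ">")
  up <- slts$labels[skey %in% c("0>1", "1>2"), , drop = FALSE]
  down <- slts$labels[skey %in% c("2>1", "1>0"), , drop = FALSE]
  expect_true(all(up[, 2]) && !any(up[, 1]))
  expect_true(all(down[, 1]) && !any(down[, 2]))
})

test_that("sat_set computes the documented toggle examples", {
  s <- toggle_setup()
  expect_identical(sum(sat_set(s$lts, EAF(alpha_assign(c(I = 0L)),
                                          f_atom("B")))), 4L)
  aag <- sat_set(s$lts, AAG(alpha_assign(c(I = 0L)), f_atom("A", "=", 0L)))
  expect_true(aag[pattern_states(s$lts, s$patterns$PB)])
  expect_true(all(sat_set(s$lts, EAF(alpha_true(), f_true()))))
  expect_error(sat_set(s$lts, EAF(alpha_atom("A"), f_true())), "non-input")
  expect_error(sat_set(s$lts, f_atom("I")), "not an internal")
  expect_error(sat_set(s$lts, f_pattern("nope")), "unknown pattern")
})

test_that("check_property follows the whole-initial-set convention", {
  s <- toggle_setup()
  e0 <- alpha_env("e0")
  v <- check_property(s$lts, "PA",
                      EAF(e0, f_and(f_pattern("PB"), AAG(e0, f_pattern("PB")))),
                      s$patterns, s$environments)
  expect_true(v$true)

  v <- check_property(s$lts, "PB", EAF(alpha_true(), f_pattern("PA")),
                      s$patterns, s$environments)
  expect_false(v$true)
  expect_identical(state_keys(v$counterexample), "0,1")

  # two initial states: one reaches PA under I=1, the stable one does not
  v <- check_property(s$lts, c(A = 0L), EAF(alpha_env("e1"), f_pattern("PA")),
                      s$patterns, s$environments)
  expect_false(v$true)
  expect_identical(v$n_init, 2L)
  expect_identical(state_keys(v$counterexample), "0,1")
  expect_identical(state_keys(v$witness), "0,0")

  expect_error(check_property(s$lts, f_false(), f_true(),
                              s$patterns, s$environments),
               "vacuous")
})

test_that("formula strings round through the parser to the same verdicts", {
  s <- toggle_setup()
  m <- toggle_model()
  pf <- parse_formula("INIT PA; EAF(e0)(PB & AAG(e0)(PB))", m,
                      s$patterns, s$environments)
  v <- check_property(s$lts, pf$init, pf$formula, s$patterns, s$environments)
  expect_true(v$true)
  pf2 <- parse_formula("INIT PB; EAF(!e0 & !e1)(PA)", m,
                       s$patterns, s$environments)
  # e0 and e1 cover both valuations, so the restriction is empty
  v2 <- check_property(s$lts, pf2$init, pf2$formula, s$patterns,
                       s$environments)
  expect_false(v2$true)
  pf3 <- parse_formula("EAU({I=1})[A<=0 U PA]", m, s$patterns,
                       s$environments)
  expect_identical(pf3$formula$type, "EAU")
  expect_true(any(sat_set(s$lts, pf3$formula, s$patterns, s$environments)))
})

test_that("AAG and EAF are dual on random labeled systems", {
  for (seed in 1:25) {
    m <- draw_battery_model(seed)
    lts <- build_lts(m)
    p <- draw_pattern(m, seed + 100L)
    a <- draw_alpha(m, lts, seed + 200L)
    phi <- if (length(p)) {
      f <- NULL
      for (nm in names(p)) {
        atm <- f_atom(nm, "=", p[[nm]])
        f <- if (is.null(f)) atm else f_and(f, atm)
      }
      f
    } else f_true()
    lhs <- sat_set(lts, AAG(a$alpha, phi))
    rhs <- !sat_set(lts, EAF(a$alpha, f_not(phi)))
    expect_identical(lhs, rhs)
  }
})

test_that("EAF is monotone in its state argument and its restriction", {
  for (seed in 1:20) {
    m <- draw_battery_model(seed)
    lts <- build_lts(m)
    p <- draw_pattern(m, seed + 300L)
    phi1 <- if (length(p)) {
      f <- NULL
      for (nm in names(p)) {
        atm <- f_atom(nm, "=", p[[nm]])
        f <- if (is.null(f)) atm else f_and(f, atm)
      }
      f
    } else f_false()
    phi2 <- if (length(p)) f_atom(names(p)[1], "=", p[[1]]) else f_true()
    a <- draw_alpha(m, lts, seed + 400L)
    # phi1 implies phi2; alpha implies true
    s1 <- sat_set(lts, EAF(a$alpha, phi1))
    s2 <- sat_set(lts, EAF(a$alpha, phi2))
    s3 <- sat_set(lts, EAF(alpha_true(), phi1))
    expect_true(all(s2[s1]))
    expect_true(all(s3[s1]))
  }
})

test_that("sat_set matches the matrix-reachability oracle on random systems", {
  for (seed in 1:30) {
    m <- draw_battery_model(seed)
    lts <- build_lts(m)
    adjs <- oracle_lts_adjs(m)
    p <- draw_pattern(m, seed + 500L)
    phi_vec <- pattern_vec(lts, p)
    phi <- if (length(p)) {
      f <- NULL
      for (nm in names(p)) {
        atm <- f_atom(nm, "=", p[[nm]])
        f <- if (is.null(f)) atm else f_and(f, atm)
      }
      f
    } else f_true()
    a <- draw_alpha(m, lts, seed + 600L)

    expect_identical(unname(sat_set(lts, EAF(a$alpha, phi))),
                     unname(oracle_EAF(adjs, a$vec, phi_vec)))
    expect_identical(unname(sat_set(lts, EAG(a$alpha, phi))),
                     unname(oracle_EAG(adjs, a$vec, phi_vec)))
    q <- draw_pattern(m, seed + 700L)
    psi_vec <- pattern_vec(lts, q)
    psi <- if (length(q)) {
      f <- NULL
      for (nm in names(q)) {
        atm <- f_atom(nm, "=", q[[nm]])
        f <- if (is.null(f)) atm else f_and(f, atm)
      }
      f
    } else f_true()
    expect_identical(unname(sat_set(lts, EAU(a$alpha, phi, psi))),
                     unname(oracle_EAU(adjs, a$vec, phi_vec, psi_vec)))
  }
})

test_that("under a single input valuation EAF reduces to CTL EF on the STG", {
  for (seed in c(2, 9, 21)) {
    m <- draw_battery_model(seed)
    ins <- m$components$name[m$components$is_input]
    if (length(ins) == 0L) next
    lts <- build_lts(m)
    vals <- ogrid(ocard(m)[ins])
    p <- draw_pattern(m, seed + 800L)
    phi_vec <- pattern_vec(lts, p)
    for (j in seq_len(nrow(vals))) {
      v <- setNames(vals[j, ], ins)
      alpha <- alpha_assign(v)
      phi <- if (length(p)) {
        f <- NULL
        for (nm in names(p)) {
          atm <- f_atom(nm, "=", p[[nm]])
          f <- if (is.null(f)) atm else f_and(f, atm)
        }
        f
      } else f_true()
      got <- sat_set(lts, EAF(alpha, phi))
      # CTL EF phi on the fixed-input STG, via plain edge reachability
      stg <- build_stg(m, inputs = v)
      key_lts <- apply(lts$states, 1L, paste, collapse = ",")
      key_stg <- apply(stg$states, 1L, paste, collapse = ",")
      n <- nrow(stg$states)
      A <- matrix(FALSE, n, n)
      if (nrow(stg$edges)) A[cbind(stg$edges$from, stg$edges$to)] <- TRUE
      R <- oclosure(A)
      phi_stg <- phi_vec[match(key_stg, key_lts)]
      ef <- drop(R %*% phi_stg) > 0
      expect_identical(unname(got[match(key_stg, key_lts)]), unname(ef))
    }
  }
})

test_that("AAX is vacuously true and EAX false at alpha-deadlocks", {
  s <- toggle_setup()
  pb <- pattern_states(s$lts, s$patterns$PB)  # stable, no outgoing edges
  expect_true(sat_set(s$lts, AAX(alpha_true(), f_false()))[pb])
  expect_false(sat_set(s$lts, EAX(alpha_true(), f_true()))[pb])
  # AAF requires an actual step at deadlocked states unless phi holds now
  expect_false(sat_set(s$lts, AAF(alpha_true(), f_pattern("PA")),
                       s$patterns)[pb])
  expect_true(sat_set(s$lts, AAF(alpha_true(), f_pattern("PB")),
                      s$patterns)[pb])
})
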