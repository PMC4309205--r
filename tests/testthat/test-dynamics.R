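test_that("asynchronous successors follow the rules one unit at a time", {
  m <- toggle_model()
  s <- successors(m, c(A = 1L, B = 0L), inputs = c(I = 0L))
  expect_identical(state_keys(s), "0,0")
  expect_identical(nrow(successors(m, c(A = 0L, B = 1L), c(I = 0L))), 0L)
  # multivalued unit step: target 2 from 0 moves to 1, not 2
  st <- successors(step_model(), c(M = 0L), c(J = 1L))
  expect_identical(state_keys(st), "1")
  expect_error(successors(m, c(A = 3L, B = 0L), c(I = 0L)), "out of range")
})

test_that("synchronous updating yields a single combined successor", {
  m <- negative_circuit_model()
  s <- successors(m, c(A = 0L, B = 0L), scheme = "synchronous")
  expect_identical(state_keys(s), "1,0")
  # deterministic synchronous cycle from (0,0)
  cyc <- c("0,0")
  st <- c(A = 0L, B = 0L)
  for (k in 1:4) {
    st <- successors(m, st, scheme = "synchronous")[1, ]
    cyc <- c(cyc, paste(st, collapse = ","))
  }
  expect_identical(cyc, c("0,0", "1,0", "1,1", "0,1", "0,0"))
})

test_that("build_stg expands exactly the reachable graph", {
  m <- toggle_model()
  stg <- build_stg(m, initial = c(A = 0L, B = 0L), inputs = c(I = 1L))
  expect_identical(nrow(stg$states), 3L)
  expect_identical(nrow(stg$edges), 2L)
  outdeg <- tabulate(stg$edges$from, nbins = 3L)
  expect_identical(sum(outdeg == 0L), 2L)  # both targets terminal

  chain <- build_stg(step_model(), initial = c(M = 0L), inputs = c(J = 1L))
  expect_identical(state_keys(chain$states), c("0", "1", "2"))
  expect_identical(nrow(chain$edges), 2L)

  lone <- build_stg(m, initial = c(A = 0L, B = 1L), inputs = c(I = 0L))
  expect_identical(nrow(lone$states), 1L)
  expect_identical(nrow(lone$edges), 0L)
})

test_that("the state cap guard aborts explicit construction", {
  expect_error(build_stg(th_demo_model(),
                         inputs = c(APC = 1L, IL12_e = 0L, IL4_e = 0L),
                         state_cap = 16),
               class = "logimc_guard_error")
})

test_that("condensation partitions states into an acyclic SCC graph", {
  m <- toggle_model()
  stg <- build_stg(m, initial = c(A = 0L, B = 0L), inputs = c(I = 1L))
  cond <- condensation(stg)
  expect_length(cond$scc, 3L)
  expect_identical(sum(cond$terminal), 2L)
  expect_true(all(lengths(cond$scc) == 1L))

  neg <- build_stg(negative_circuit_model())
  cn <- condensation(neg)
  expect_identical(sum(cn$terminal), 1L)
  expect_identical(lengths(cn$scc)[cn$terminal], 4L)

  # empty-edge STG: every state its own terminal SCC
  still <- build_stg(toggle_model(), initial = c(A = 0L, B = 1L),
                     inputs = c(I = 0L))
  cs <- condensation(still)
  expect_true(all(cs$terminal))

  # no directed cycles among SCC nodes: edges go to lower (earlier) ids in
  # reverse topological numbering
  expect_true(all(cond$edges$from > cond$edges$to))
})

test_that("attractors are the terminal SCCs, classified by size", {
  att <- attractors(build_stg(toggle_model(), inputs = c(I = 1L)))
  expect_length(att, 2L)
  expect_setequal(vapply(att, `[[`, character(1), "kind"),
                  c("stable_state", "stable_state"))
  expect_setequal(unlist(lapply(att, function(a) state_keys(a$states))),
                  c("0,1", "1,0"))

  att <- attractors(build_stg(negative_circuit_model()))
  expect_length(att, 1L)
  expect_identical(att[[1]]$kind, "cyclic")
  expect_identical(nrow(att[[1]]$states), 4L)

  att <- attractors(build_stg(step_model(), inputs = c(J = 0L)))
  expect_length(att, 1L)
  expect_identical(state_keys(att[[1]]$states), "0")
})

test_that("asynchronous edges change exactly one component by one level", {
  for (seed in 1:25) {
    m <- draw_battery_model(seed)
    ins <- m$components$name[m$components$is_input]
    card_in <- ocard(m)[ins]
    vals <- ogrid(card_in)
    j <- 1L + (seed %% nrow(vals))
    v <- if (length(ins)) setNames(vals[j, ], ins) else NULL
    stg <- build_stg(m, inputs = v)
    if (nrow(stg$edges) == 0L) next
    d <- abs(stg$states[stg$edges$from, , drop = FALSE] -
               stg$states[stg$edges$to, , drop = FALSE])
    expect_true(all(rowSums(d) == 1L))
    expect_true(all(d <= 1L))
    # synchronous STG: out-degree at most one everywhere
    sy <- build_stg(m, inputs = v, scheme = "synchronous")
    expect_true(all(tabulate(sy$edges$from, nbins = nrow(sy$states)) <= 1L))
  }
})

test_that("attractors match the mutual-reachability oracle on random models", {
  for (seed in 1:30) {
    m <- draw_battery_model(seed)
    ins <- m$components$name[m$components$is_input]
    card_in <- ocard(m)[ins]
    vals <- ogrid(card_in)
    for (j in seq_len(nrow(vals))) {
      v <- if (length(ins)) setNames(vals[j, ], ins) else NULL
      oa <- oracle_adjacency(m, v)
      want <- lapply(oracle_terminal_scc(oa$adj), function(ix)
        state_keys(oa$states[ix, , drop = FALSE]))
      att <- attractors(build_stg(m, inputs = v))
      got <- lapply(att, function(a) state_keys(a$states))
      expect_setequal(got, want)
    }
  }
})

test_that("DOT export marks stable states and terminal SCCs", {
  stg <- build_stg(toggle_model(), inputs = c(I = 1L))
  dot <- export_stg_dot(stg)
  expect_identical(sum(grepl("peripheries=2", dot)), 2L)
  expect_true(any(grepl("fillcolor", dot)))
  dot2 <- export_stg_dot(stg, what = "condensation")
  expect_true(any(grepl("->", dot2)))
})
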