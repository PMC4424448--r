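mk_inst <- function(source, effect, target, s_state) {
  data.frame(source = source, effect = effect, target = target,
             source_state = as.integer(s_state),
             target_state = as.integer(ifelse(effect == "activation",
                                              s_state, -s_state)),
             stringsAsFactors = FALSE)
}

# sample networks holding the given instances; pad with empty networks
mk_nets <- function(..., n_empty = 0) {
  nets <- c(list(...), replicate(n_empty, mk_inst(character(0),
            character(0), character(0), integer(0)), simplify = FALSE))
  names(nets) <- paste0("s", seq_along(nets))
  class(nets) <- "dera_sample_networks"
  nets
}

i_ab <- mk_inst("A", "activation", "B", 1)
i_bc <- mk_inst("B", "activation", "C", -1)
i_de <- mk_inst("D", "inhibition", "E", 1)

test_that("frequency_table counts over all samples including empty ones", {
  nets <- mk_nets(rbind(i_ab, i_bc), i_ab, n_empty = 2)  # 4 samples
  ft <- frequency_table(nets)
  expect_equal(attr(ft, "group_size"), 4L)
  expect_equal(ft$frequency[ft$source == "A"], 0.5)
  expect_equal(ft$frequency[ft$source == "B"], 0.25)
  # instance in every sample -> frequency 1
  ft2 <- frequency_table(mk_nets(i_ab, i_ab, i_ab))
  expect_equal(ft2$frequency, 1)
  expect_error(frequency_table(list()), "no sample networks")
})

test_that("frequency_table equals an independent nested-iteration tally", {
  set.seed(202)
  for (rep in 1:5) {
    net <- as_network(rand_reg(25, 35))
    ind <- rand_indicator(paste0("g", 1:25), 20)
    nets <- suppressWarnings(induce_all(net, ind))
    ft <- frequency_table(nets)
    ref <- oracle_freq(lapply(names(nets), function(s)
      oracle_induce_keys(net$regulations, ind, s)))
    got <- data.frame(key = paste(ft$source, ft$effect, ft$target,
                                  ft$source_state, ft$target_state,
                                  sep = "|"),
                      count = ft$count, frequency = ft$frequency)
    got <- got[order(got$key), ]
    expect_equal(got$key, ref$key)
    expect_equal(got$count, ref$count)
    expect_equal(got$frequency, ref$frequency)
  }
})

test_that("identify_core keeps frequency >= T inclusively", {
  nets <- mk_nets(rbind(i_ab, i_bc, i_de), rbind(i_ab, i_bc),
                  rbind(i_ab, i_de), i_ab, n_empty = 1)  # 5 samples
  ft <- frequency_table(nets)  # A:0.8 B:0.4 D:0.4... adjust below
  core <- identify_core(ft, T = 0.4)
  expect_setequal(core$source, c("A", "B", "D"))
  core2 <- identify_core(ft, T = 0.5)
  expect_equal(core2$source, "A")
  core3 <- identify_core(ft, T = 1.0)
  expect_equal(nrow(core3), 0L)
  expect_error(identify_core(ft, T = 0), "T")
  expect_error(identify_core(ft, T = 1.5), "T")
})

test_that("t_sweep counts non-increasing core sizes over the grid", {
  nets <- mk_nets(rbind(i_ab, i_bc, i_de), rbind(i_ab, i_bc), i_ab,
                  n_empty = 7)  # freqs 0.3, 0.2, 0.1
  ft <- frequency_table(nets)
  sw <- t_sweep(ft, c(0.25, 0.05, 0.15))
  expect_equal(sw$T, c(0.05, 0.15, 0.25))
  expect_equal(sw$size, c(3L, 2L, 1L))
  expect_true(all(diff(sw$size) <= 0))
  sw1 <- t_sweep(ft, 0.15)
  expect_equal(sw1$size, nrow(identify_core(ft, 0.15)))
  expect_error(t_sweep(ft, c(0.5, 0)), "T values")
  # random grids match a direct recount
  set.seed(8)
  net <- as_network(rand_reg(20, 40))
  ind <- rand_indicator(paste0("g", 1:20), 15)
  ftr <- frequency_table(suppressWarnings(induce_all(net, ind)))
  grid <- sort(runif(20, 0.01, 1))
  swr <- t_sweep(ftr, grid)
  expect_equal(swr$size,
               vapply(grid, function(T) sum(ftr$frequency >= T), integer(1)))
})

test_that("find_subnetworks labels components by size then gene order", {
  nets <- mk_nets(rbind(i_ab, i_bc, i_de))
  core <- identify_core(frequency_table(nets), T = 0.5)
  core <- find_subnetworks(core)
  expect_equal(attr(core, "n_components"), 2L)
  # {A,B,C} is larger than {D,E} so gets component 1
  expect_equal(core$component_id[core$source %in% c("A", "B")], c(1L, 1L))
  expect_equal(core$component_id[core$source == "D"], 2L)
  # empty core: zero components
  empty <- identify_core(frequency_table(mk_nets(n_empty = 2)), T = 0.5)
  expect_equal(attr(find_subnetworks(empty), "n_components"), 0L)
})

test_that("component partition agrees with a brute-force union-find", {
  set.seed(303)
  for (rep in 1:20) {
    reg <- rand_reg(30, sample(5:50, 1))
    reg <- unique(reg)
    inst <- mk_inst(reg$source, reg$effect, reg$target,
                    sample(c(-1, 1), nrow(reg), replace = TRUE))
    core <- identify_core(frequency_table(mk_nets(inst)), T = 0.5)
    core <- find_subnetworks(core)
    ref <- oracle_components(core$source, core$target)
    # same partition: every package component equals one oracle component
    got <- split(c(core$source, core$target),
                 c(core$component_id, core$component_id))
    got <- lapply(got, function(g) sort(unique(g)))
    ref <- lapply(unname(ref), sort)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(ref, paste, collapse = ","))
    # edge counts over components sum to the core size
    expect_equal(sum(table(core$component_id)), nrow(core))
  }
})

test_that("group_specific subtracts other groups at the instance level", {
  i1 <- i_ab; i2 <- i_bc; i3 <- i_de
  core_t <- identify_core(frequency_table(mk_nets(rbind(i1, i2))), 0.5,
                          group_label = "target")
  core_o1 <- identify_core(frequency_table(mk_nets(i2)), 0.5)
  core_o2 <- identify_core(frequency_table(mk_nets(n_empty = 1)), 0.5)
  out <- group_specific(core_t, list(core_o1, core_o2))
  expect_equal(out$source, "A")
  # others empty -> target unchanged
  out2 <- group_specific(core_t, list(core_o2))
  expect_equal(nrow(out2), 2L)
  # instance level: same edge with flipped sign elsewhere stays specific
  i1_flip <- mk_inst("A", "activation", "B", -1)
  core_o3 <- identify_core(frequency_table(mk_nets(i1_flip)), 0.5)
  out3 <- group_specific(core_t, list(core_o3))
  expect_true("A" %in% out3$source)
  # ... but is removed under edge-level comparison
  out4 <- group_specific(core_t, list(core_o3), level = "edge")
  expect_false("A" %in% out4$source)
  # result is disjoint from every other group's core
  k <- function(x) paste(x$source, x$effect, x$target, x$source_state)
  expect_length(intersect(k(out), k(core_o1)), 0L)
})

test_that("cross_cohort_validate thresholds then intersects", {
  core_d <- identify_core(frequency_table(mk_nets(rbind(i_ab, i_bc),
                                                  rbind(i_ab, i_bc))), 0.5)
  # validation cohort: i_ab in 9/20, i_bc in 6/20
  vnets <- mk_nets(rbind(i_ab, i_bc), rbind(i_ab, i_bc), rbind(i_ab, i_bc),
                   rbind(i_ab, i_bc), rbind(i_ab, i_bc), rbind(i_ab, i_bc),
                   i_ab, i_ab, i_ab, n_empty = 11)
  res <- cross_cohort_validate(core_d, vnets, T_validation = 0.4)
  expect_equal(res$validated$source, "A")   # 0.45 >= 0.4; 0.30 < 0.4
  expect_equal(res$report$validation_frequency, c(0.45, 0.30))
  expect_equal(res$report$validated, res$report$source == "A")
  # self-validation identity: same cohort, same T
  nets <- mk_nets(rbind(i_ab, i_de), rbind(i_ab, i_de), i_ab, n_empty = 1)
  core <- identify_core(frequency_table(nets), 0.5)
  res2 <- cross_cohort_validate(core, nets, 0.5)
  expect_identical(inst_keys(res2$validated), inst_keys(core))
  expect_true(all(res2$report$validated))
  expect_error(cross_cohort_validate(core, list(), 0.5), "empty")
})

test_that("regulation_expression sums the two genes' fold changes", {
  fc <- matrix(c(1.5, 2.0, 1.0, -1.0), 2, 2,
               dimnames = list(c("A", "B"), c("s1", "s2")))
  inst <- mk_inst("A", "activation", "B", 1)
  expect_equal(regulation_expression(fc, inst, "s1"), 3.5)
  expect_equal(regulation_expression(fc, inst, "s2"), 0.0)
  expect_error(regulation_expression(fc, mk_inst("A", "activation", "Z", 1),
                                     "s1"), "Z")
  # brute-force re-computation over random instances and samples
  set.seed(5)
  fcr <- matrix(rnorm(50), 10, 5, dimnames = list(paste0("g", 1:10),
                                                  paste0("s", 1:5)))
  for (r in 1:10) {
    gs <- sample(rownames(fcr), 2)
    s <- sample(colnames(fcr), 1)
    inst <- mk_inst(gs[1], "inhibition", gs[2], 1)
    expect_equal(regulation_expression(fcr, inst, s),
                 fcr[gs[1], s] + fcr[gs[2], s])
  }
})

test_that("threshold monotonicity: cores are nested as T grows", {
  set.seed(17)
  net <- as_network(rand_reg(25, 40))
  ind <- rand_indicator(paste0("g", 1:25), 20)
  ft <- frequency_table(suppressWarnings(induce_all(net, ind)))
  Ts <- sort(runif(6, 0.05, 1))
  for (i in seq_len(length(Ts) - 1)) {
    lo <- identify_core(ft, Ts[i]); hi <- identify_core(ft, Ts[i + 1])
    expect_true(all(inst_keys(hi) %in% inst_keys(lo)))
  }
})

test_that("core sets round-trip through write_core_set/read_core_set", {
  nets <- mk_nets(rbind(i_ab, i_bc, i_de))
  core <- find_subnetworks(identify_core(frequency_table(nets), 0.5))
  f <- withr::local_tempfile(); fs <- withr::local_tempfile()
  fn <- withr::local_tempfile()
  write_core_set(core, f, sif_path = fs, nodes_path = fn)
  back <- read_core_set(f)
  expect_equal(as.data.frame(back), as.data.frame(core),
               ignore_attr = TRUE)
  sif <- readLines(fs)
  expect_length(sif, 3L)
  nodes <- read.delim(fn)
  expect_setequal(nodes$gene, c("A", "B", "C", "D", "E"))
})
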