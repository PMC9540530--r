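# Status-category algebra: assemblages, loss/gain sets, subgroups.

makeStatus <- function(df) StatusTable(df)

simpleRegion <- function() {
  data.frame(
    species_id = c("a", "b", "c", "d", "e", "f", "c"),
    region_id = "r1",
    category = c("NATIVE_PERSISTING", "NATIVE_EXTIRPATED", "NATIVE_REGAINED",
                 "NATIVE_COLONIST", "INTRODUCED", "FUTURE_POTENTIAL",
                 "FUTURE_POTENTIAL"),
    recent = c(NA, FALSE, TRUE, FALSE, TRUE, NA, NA),
    stringsAsFactors = FALSE)
}

test_that("assemble reconstructs the species set at each timepoint", {
  st <- makeStatus(simpleRegion())
  expect_setequal(speciesIds(assemble(st, "r1", "BP8000")), c("a", "b", "c"))
  expect_setequal(speciesIds(assemble(st, "r1", "Y2020")),
                  c("a", "c", "d", "e"))
  # 1945: b extirpated pre-1945 (gone), c regained post-1945 (still absent),
  # d colonised pre-1945 (present), e introduced post-1945 (absent)
  expect_setequal(speciesIds(assemble(st, "r1", "Y1945")), c("a", "d"))
  expect_setequal(speciesIds(assemble(st, "r1", "FUTURE")),
                  c("a", "c", "d", "e", "f"))
  # empty record set gives an empty assemblage
  empty <- makeStatus(simpleRegion()[0, ])
  expect_length(speciesIds(assemble(empty, "r1", "BP8000")), 0)
  # errors
  expect_error(assemble(st, "r1", "Y1999"), "timepoint")
  expect_error(assemble(st, "nowhere", "Y2020", knownRegions = "r1"),
               "unknown region")
})

test_that("loss/gain sets satisfy the turnover identity", {
  st <- makeStatus(simpleRegion())
  lg <- lossGainSets(st, "r1")
  expect_setequal(lg$loss, c("b", "c"))   # regained species count as lost
  expect_setequal(lg$gain, c("c", "d", "e"))
  s0 <- speciesIds(assemble(st, "r1", "BP8000"))
  s1 <- speciesIds(assemble(st, "r1", "Y2020"))
  expect_setequal(union(setdiff(s0, lg$loss), lg$gain), s1)

  # a no-change region yields empty sets
  quiet <- makeStatus(data.frame(
    species_id = c("a", "b"), region_id = "rq",
    category = "NATIVE_PERSISTING", recent = NA, stringsAsFactors = FALSE))
  lgq <- lossGainSets(quiet, "rq")
  expect_length(lgq$loss, 0)
  expect_length(lgq$gain, 0)

  # identity holds across a whole simulated batch
  bundle <- simulateFauna(simulationConfig(seed = 71, n_species = 60,
                                           n_trees = 2, n_regions = 12))
  for (r in regionIds(bundle)) {
    lg <- lossGainSets(bundle, r)
    s0 <- speciesIds(assemble(bundle, r, "BP8000"))
    s1 <- speciesIds(assemble(bundle, r, "Y2020"))
    expect_setequal(union(setdiff(s0, lg$loss), lg$gain), s1)
  }
})

test_that("1945 assemblage matches a brute-force replay of era flags", {
  bundle <- simulateFauna(simulationConfig(seed = 72, n_species = 50,
                                           n_trees = 2, n_regions = 8))
  df <- statusData(bundle)
  for (r in regionIds(bundle)) {
    rows <- df[df$region_id == r & df$category != "FUTURE_POTENTIAL", ]
    present <- vapply(seq_len(nrow(rows)), function(i) {
      switch(rows$category[i],
             NATIVE_PERSISTING = TRUE,
             NATIVE_EXTIRPATED = rows$recent[i],        # lost after 1945
             NATIVE_REGAINED = !rows$recent[i],          # back by 1945
             NATIVE_COLONIST = !rows$recent[i],
             INTRODUCED = !rows$recent[i])
    }, logical(1))
    expect_setequal(speciesIds(assemble(bundle, r, "Y1945")),
                    rows$species_id[present])
  }
})

test_that("status table validity enforces uniqueness and era flags", {
  dup <- rbind(simpleRegion(),
               data.frame(species_id = "a", region_id = "r1",
                          category = "INTRODUCED", recent = TRUE))
  expect_error(StatusTable(dup), "duplicate")
  flagged <- simpleRegion(); flagged$recent[1] <- TRUE
  expect_error(StatusTable(flagged), "recent")
  missing <- simpleRegion(); missing$recent[2] <- NA
  expect_error(StatusTable(missing), "recent")
  # the future overlay may coexist with a historic record (row 7 vs row 3)
  expect_s4_class(makeStatus(simpleRegion()), "StatusTable")
})

test_that("mass/volancy subgroups partition the non-volant species", {
  df <- toySpecies(sprintf("s%02d", 1:6),
                   mass = c(10, 1999.9, 2000, 2000.1, 5e4, 10),
                   volant = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  sp <- SpeciesTable(df)
  large <- subgroupFilter(sp, "large_nonvolant")
  small <- subgroupFilter(sp, "small_nonvolant")
  expect_setequal(large, c("s04", "s05"))
  expect_setequal(small, c("s01", "s02", "s03"))    # 2 kg exactly is small
  expect_false("s06" %in% c(large, small))          # volant excluded
  expect_setequal(union(large, small), df$species_id[!df$volant])
  expect_length(intersect(large, small), 0)
  expect_identical(subgroupFilter(sp, "all"), df$species_id)
  df$mass_g[2] <- NA
  expect_error(subgroupFilter(df, "large_nonvolant"), "s02")
})
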