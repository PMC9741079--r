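test_that("channel profile and node invariants are enforced", {
  expect_error(sphere_nodes(0, 0, 0, 0), "radii")
  expect_error(sphere_nodes(c(0, 1), c(0, 0), c(0, Inf), c(1, 1)), "finite")
  expect_error(channel_profile("c", data.frame(x = 0, y = 0, z = 0, r = 1)),
               "at least 2 nodes")
  expect_error(channel_profile("c", data.frame(x = c(0, 0), y = c(0, 0),
                                               z = c(1, 1), r = c(1, 1))),
               "distinct")
  p <- channel_profile("c", data.frame(x = c(0, 1), y = 0, z = 0, r = c(1, 2)))
  expect_s3_class(p, "channel_profile")
  expect_equal(nrow(p$nodes), 2)
})

test_that("a minimal profile JSON file parses to one set with one 2-node channel", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"protein_id":"p1","species":"Methanocaldococcus jannaschii",
    "enzyme":"Mmr","subunit":"alpha","source":"predicted",
    "channels":[{"channel_id":"T1",
      "nodes":[{"x":0,"y":0,"z":0,"r":1.5},{"x":0,"y":0,"z":3,"r":1.2}]}]}]',
    path)
  sets <- read_profile_json(path)
  expect_length(sets, 1)
  expect_equal(sets[[1]]$protein_id, "p1")
  expect_length(sets[[1]]$channels, 1)
  expect_equal(sets[[1]]$channels[[1]]$nodes$r, c(1.5, 1.2))
})

test_that("profile JSON rejects non-positive radii and malformed records", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"protein_id":"p1","species":"s","enzyme":"Mmr","subunit":"a",
    "source":"predicted","channels":[{"channel_id":"T1",
    "nodes":[{"x":0,"y":0,"z":0,"r":0},{"x":0,"y":0,"z":1,"r":1}]}]}]', path)
  expect_error(read_profile_json(path), "radius must be > 0")
  writeLines('[{"protein_id":"p1","species":"s"}]', path)
  expect_error(read_profile_json(path), "missing field")
  writeLines('{"not": "an array', path)
  expect_error(read_profile_json(path), "malformed")
})

test_that("profile JSON write/read round trip is the identity on random sets", {
  for (seed in 1:5) {
    set.seed(seed)
    sets <- lapply(1:3, function(i) {
      chans <- lapply(seq_len(sample(1:3, 1)), function(j)
        random_profile(n_nodes = sample(3:9, 1), seed = seed * 100 + i * 10 + j,
                       id = paste0("T", j)))
      protein_channel_set(paste0("p", i), paste0("species_", i),
                          sample(c("Mmr", "Hdr"), 1), "alpha",
                          sample(c("predicted", "resolved"), 1), chans)
    })
    path <- withr::local_tempfile(fileext = ".json")
    write_profile_json(sets, path)
    back <- read_profile_json(path)
    expect_equal(back, sets)
  }
})

test_that("profile CSV reader groups contiguous rows and rejects interleaving", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("channel_id,x,y,z,r",
               "T1,0,0,0,1.5", "T1,0,0,2,1.4", "T1,0,0,4,1.2"), path)
  profs <- read_profile_csv(path)
  expect_length(profs, 1)
  expect_equal(nrow(profs[["T1"]]$nodes), 3)
  expect_equal(profs[["T1"]]$nodes$r, c(1.5, 1.4, 1.2))

  writeLines(c("channel_id,x,y,z,r",
               "T1,0,0,0,1", "T2,5,0,0,1", "T1,0,0,2,1", "T2,5,0,2,1"), path)
  expect_error(read_profile_csv(path), "not contiguous")

  writeLines(c("channel_id,x,y,z", "T1,0,0,0"), path)
  expect_error(read_profile_csv(path), "missing required column")
})

test_that("profile CSV round trip reproduces the generating profiles", {
  profs <- lapply(1:4, function(i) random_profile(6, seed = 40 + i,
                                                  id = paste0("T", i)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(profs, path)
  back <- read_profile_csv(path)
  expect_equal(unname(back), profs)
})

test_that("PDB reading assigns per-element van der Waals radii", {
  atoms <- atom_set(x = c(0, 2, 4, 6), y = 0, z = 0, vdw = 1,
                    name = c("C", "N", "O", "S"),
                    element = c("C", "N", "O", "S"))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(atoms, path)
  back <- read_structure_pdb(path)
  expect_equal(nrow(back), 4)
  expect_equal(back$vdw, c(1.70, 1.55, 1.52, 1.80))
  expect_equal(back$x, atoms$x, tolerance = 1e-3)  # PDB has 3 decimals
})

test_that("PDB reading warns and defaults the radius for unknown elements", {
  atoms <- atom_set(x = 0, y = 0, z = 0, vdw = 1, name = "FE", element = "FE")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(atoms, path)
  expect_warning(back <- read_structure_pdb(path), "unknown element")
  expect_equal(back$vdw, 1.70)
})

test_that("PDB reading errors when there are no atom records", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    EMPTY", "END"), path)
  expect_error(read_structure_pdb(path))
})

test_that("synthetic tube PDB round trips with the generator's atom count", {
  tube <- generate_tube_structure(tube_spec(length = 12, radius = 2, seed = 9))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(tube$atoms, path)
  back <- read_structure_pdb(path)
  expect_equal(nrow(back), nrow(tube$atoms))
  expect_equal(back$vdw, tube$atoms$vdw)
})

test_that("dataset tables assign temperature classes and validate inputs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tenzyme\tsubunit\tt_opt\tlength\tsurface\tvolume",
               "Methanomicrobium mobile\tMmr\talpha\t37\t100\t2000\t3000",
               "Methanopyrus sp. KOL6\tMmr\talpha\t110\t90\t1900\t2800"), path)
  ds <- read_dataset_table(path)
  expect_s3_class(ds, "measurement_dataset")
  expect_equal(ds$t_class, c("<50", ">80"))

  writeLines("species\tenzyme\tsubunit\tt_opt\tlength\tsurface\tvolume", path)
  empty <- read_dataset_table(path)
  expect_equal(nrow(empty), 0)

  writeLines(c("species\tenzyme\tsubunit\tt_opt\tlength\tsurface\tvolume",
               "sp\tMmr\talpha\twarm\t1\t1\t1"), path)
  expect_error(read_dataset_table(path), "non-numeric t_opt at row 1")

  writeLines(c("species\tenzyme\tsubunit\tt_opt\tlength\tsurface\tvolume",
               "sp\tMmr\talpha\t37\t-1\t1\t1"), path)
  expect_error(read_dataset_table(path), ">= 0")
})

test_that("external tables are ingested through a column mapping", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("Species name", "Enzyme", "Subunit", "Topt (C)",
                     "L (A)", "S (A2)", "V (A3)", sep = "\t"),
               paste("Methanosarcina barkeri", "Mmr", "alpha", "37",
                     "120", "2100", "3300", sep = "\t")), path)
  ds <- read_dataset_table(path, col_map = c(
    species = "Species name", enzyme = "Enzyme", subunit = "Subunit",
    t_opt = "Topt (C)", length = "L (A)", surface = "S (A2)",
    volume = "V (A3)"))
  expect_equal(ds$t_class, "<50")
  expect_equal(ds$length, 120)
  expect_error(read_dataset_table(path, col_map = c(species = "nope")),
               "not in the file")
})

test_that("dataset table round trips through TSV", {
  ds <- generate_dimension_dataset(dimension_gen_spec(n_per_class = 3, seed = 11))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset_table(ds, path)
  back <- read_dataset_table(path)
  expect_equal(back$species, ds$species)
  expect_equal(back$t_class, ds$t_class)
  expect_equal(back$volume, ds$volume, tolerance = 1e-12)
})
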