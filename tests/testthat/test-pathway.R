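# Candidate selection, monophyly validation, presence calls, and Dollo
# parsimony loss mapping.

test_that("candidate selection unions top bit-score and top identity hits", {
  hits <- data.frame(query = "q1",
                     subject = paste0("s", 1:10),
                     pident = c(90, 80, 70, 60, 50, 40, 30, 20, 10, 5),
                     bitscore = c(5, 10, 20, 30, 40, 50, 60, 70, 80, 90),
                     stringsAsFactors = FALSE)
  got <- select_candidates(hits, k = 3)
  expect_equal(got$q1, sort(c("s10", "s9", "s8", "s1", "s2", "s3")))

  # coincident rankings select exactly k
  hits2 <- hits
  hits2$bitscore <- hits2$pident
  expect_equal(select_candidates(hits2, k = 3)$q1, c("s1", "s2", "s3"))

  two <- hits[1:2, ]
  expect_equal(select_candidates(two, k = 3)$q1, c("s1", "s2"))

  expect_length(select_candidates(hits[0, ], k = 3), 0L)

  # ties broken by subject id order; cross-check against a sort oracle
  set.seed(44)
  for (i in 1:5) {
    h <- data.frame(query = "q",
                    subject = sample(paste0("x", 1:12)),
                    pident = sample(60:70, 12, replace = TRUE),
                    bitscore = sample(100:110, 12, replace = TRUE),
                    stringsAsFactors = FALSE)
    want <- sort(union(
      h$subject[order(-h$bitscore, h$subject)][1:3],
      h$subject[order(-h$pident, h$subject)][1:3]))
    expect_equal(select_candidates(h, k = 3)$q, want)
  }
})

test_that("ortholog validation finds the maximal reference clade", {
  t1 <- read_newick(text = "((ref,cand1),outparalog);")
  expect_equal(validate_orthologs(t1, "ref", "cand1"), "cand1")

  t2 <- read_newick(text = "((ref,outparalog),cand1);")
  expect_equal(validate_orthologs(t2, "ref", "cand1"), character(0))

  expect_error(validate_orthologs(t1, "nope", "cand1"), "not a leaf")

  # random trees against a brute-force maximal-clade search
  set.seed(52)
  for (i in 1:8) {
    tr <- ape::rtree(9, tip.label = paste0("L", 1:9))
    ref <- "L1"
    cands <- sample(paste0("L", 2:9), 4)
    got <- validate_orthologs(tr, ref, cands)
    allowed <- c(ref, cands)
    best <- ref
    for (cl in oracle_clades(tr)) {
      if (ref %in% cl && all(cl %in% allowed) && length(cl) > length(best))
        best <- cl
    }
    expect_equal(got, sort(intersect(best, cands)))
  }
})

test_that("presence calls respect data-type evidence", {
  taxa <- rhodophyta_taxa()
  validated <- list(HMGR = c("Galdieria_sulphuraria", "Rhodosorus_marinus"))
  M <- call_presence(validated, taxa)  # default: transcriptome absence is "?"
  expect_equal(M["HMGR", "Galdieria_sulphuraria"], "P")
  expect_equal(M["HMGR", "Chondrus_crispus"], "A")           # whole genome
  expect_equal(M["HMGR", "Calliarthron_tuberculosum"], "A")  # partial genome
  expect_equal(M["HMGR", "Palmaria_palmata"], "?")           # transcriptome

  Ma <- call_presence(validated, taxa, transcriptome_absence = "absent")
  expect_equal(Ma["HMGR", "Palmaria_palmata"], "A")

  bad <- taxa
  bad$data_type[3] <- NA
  expect_error(call_presence(validated, bad), "data_type")
  expect_error(call_presence(list(g = "Martian"), taxa), "Martian")
})

test_that("pathway-level calls aggregate core enzymes by majority", {
  taxa <- rhodophyta_taxa()
  validated <- list(
    ACAT = taxa$taxon_id, HMGS = taxa$taxon_id,
    HMGR = "Galdieria_sulphuraria",
    MVK = c("Galdieria_sulphuraria", "Rhodosorus_marinus"),
    PMK = c("Galdieria_sulphuraria", "Rhodosorus_marinus"),
    MVD = "Rhodosorus_marinus",
    IDI = taxa$taxon_id)
  M <- call_presence(validated, taxa, transcriptome_absence = "absent")
  pw <- pathway_call(M)  # core HMGR..MVD, majority = 2 of 4
  expect_true(pw[["Galdieria_sulphuraria"]])   # 3 core enzymes present
  expect_true(pw[["Rhodosorus_marinus"]])      # 3 core enzymes present
  expect_false(pw[["Chondrus_crispus"]])       # none
  expect_error(pathway_call(M[1:2, ], enzymes = c("HMGR", "MVK")), "absent")
})

test_that("Dollo mapping places minimal losses (worked 15-taxon example)", {
  sp <- rhodophyta_tree()
  present <- c("Galdieria_sulphuraria", "Rhodosorus_marinus",
               "Purpureofilum_apyrenoidigerum")
  states <- stats::setNames(
    ifelse(sp$tip.label %in% present, "present", "absent"), sp$tip.label)
  dm <- dollo_losses(sp, states)
  expect_equal(dm$loss_count, 3L)
  seaweeds <- sort(c("Calliarthron_tuberculosum", "Chondrus_crispus",
                     "Hildenbrandia_rubra", "Palmaria_palmata",
                     "Porphyra_umbilicalis"))
  nonstylo <- sort(c("Compsopogon_coeruleus", "Rhodochaete_pulchella",
                     "Rhodella_maculata", "Porphyridium_purpureum",
                     "Erythrolobus_australicus", "Timspurckia_oligopyrenoides"))
  expect_true(list(seaweeds) %in% dm$losses)
  expect_true(list(nonstylo) %in% dm$losses)
  expect_true(list("Cyanidioschyzon_merolae") %in% dm$losses)

  # all present: no losses
  all_p <- stats::setNames(rep("present", 15), sp$tip.label)
  expect_equal(dollo_losses(sp, all_p)$loss_count, 0L)

  # exactly one absent leaf: one loss on its terminal branch
  one <- all_p
  one["Chondrus_crispus"] <- "absent"
  dm1 <- dollo_losses(sp, one)
  expect_equal(dm1$losses, list("Chondrus_crispus"))

  none <- stats::setNames(rep("absent", 15), sp$tip.label)
  expect_error(dollo_losses(sp, none), "no present leaf")
})

test_that("Dollo loss counts match exhaustive loss-subset minimization", {
  set.seed(61)
  for (i in 1:6) {
    tr <- ape::rtree(8, tip.label = paste0("x", 1:8))
    repeat {
      st <- sample(c("present", "absent", "ambiguous"), 8,
                   replace = TRUE, prob = c(0.5, 0.35, 0.15))
      if (any(st == "present")) break
    }
    states <- stats::setNames(st, tr$tip.label)
    dm <- dollo_losses(tr, states)
    expect_equal(dm$loss_count,
                 oracle_dollo_count(tr, states, dm$gain))
    # validity: losses lie inside the gain clade, none above a present leaf
    for (l in dm$losses) {
      expect_true(all(l %in% dm$gain))
      expect_false(any(states[l] == "present"))
    }
    # reconstruction: gain + losses reproduce the leaf states
    lost <- unlist(dm$losses)
    impl <- ifelse(tr$tip.label %in% dm$gain &
                     !(tr$tip.label %in% lost), "present", "absent")
    names(impl) <- tr$tip.label
    strict <- states[states != "ambiguous"]
    expect_identical(impl[names(strict)], strict)
    # necessity: dropping any loss edge leaves an absence unexplained
    for (j in seq_along(dm$losses))
      expect_true(any(states[dm$losses[[j]]] == "absent"))
  }
})

test_that("loss count is invariant to resolution within same-state clades", {
  # the two trees differ only in how an all-absent clade is resolved
  ta <- read_newick(text = "(((a1,(a2,a3)),p1),(p2,q1));")
  tb <- read_newick(text = "((((a1,a2),a3),p1),(p2,q1));")
  states <- c(a1 = "absent", a2 = "absent", a3 = "absent",
              p1 = "present", p2 = "present", q1 = "absent")
  expect_equal(dollo_losses(ta, states)$loss_count,
               dollo_losses(tb, states)$loss_count)
})

test_that("root-forced gains cover characters presumed ancestral", {
  tr <- read_newick(text = "((a,b),(c,d));")
  states <- c(a = "present", b = "absent", c = "absent", d = "absent")
  # default gain at MRCA of present = the leaf itself, no losses
  expect_equal(dollo_losses(tr, states)$loss_count, 0L)
  # forcing the gain to the root requires losses for the absent clades
  dmr <- dollo_losses(tr, states, gain = "root")
  expect_equal(dmr$loss_count, 2L)
  expect_true(list("b") %in% dmr$losses)
  expect_true(list(c("c", "d")) %in% dmr$losses)
})

test_that("hit tables parse from outfmt-6 and validate ranges", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "HMGR\tGaldieria_sulphuraria|g1\t91.2\t500\t44\t0\t1\t500\t1\t500\t1e-80\t800",
    "HMGR\tChondrus_crispus|g7\t35.0\t400\t260\t3\t10\t400\t5\t380\t1e-10\t120"),
    f)
  h <- read_hit_table(f)
  expect_equal(h$taxon, c("Galdieria_sulphuraria", "Chondrus_crispus"))
  expect_equal(h$bitscore, c(800, 120))
  writeLines("q\ts\t150\t1\t1\t1\t1\t1\t1\t1\t0\t10", f)
  expect_error(read_hit_table(f), "identity")
})

test_that("dollo_report tabulates losses per gene", {
  sp <- rhodophyta_tree()
  taxa <- rhodophyta_taxa()
  present <- c("Galdieria_sulphuraria", "Rhodosorus_marinus",
               "Purpureofilum_apyrenoidigerum")
  validated <- stats::setNames(
    rep(list(present), 4), c("HMGR", "MVK", "PMK", "MVD"))
  M <- call_presence(validated, taxa, transcriptome_absence = "absent")
  M <- M[, sp$tip.label]  # species-tree taxa only (greens have no tree leaf)
  rep <- dollo_report(sp, M)
  expect_equal(rep$loss_count, rep(3L, 4))
  expect_equal(rep$gene, c("HMGR", "MVK", "PMK", "MVD"))
})
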