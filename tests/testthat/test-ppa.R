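test_that("monophyly classification distinguishes the three statuses", {
  tr <- ape::read.tree(text = "(((A,B),(C,D)),(E,F));")
  expect_equal(monophyly_status(tr, c("A", "B"))$status, "monophyletic")
  expect_equal(monophyly_status(tr, "A")$status, "monophyletic")
  # clade minus a nested clade
  expect_equal(monophyly_status(tr, c("A", "B", "C", "D", "E"))$status,
               "paraphyletic")
  # both the group and its complement are scattered
  v <- monophyly_status(tr, c("A", "C"))
  expect_equal(v$status, "polyphyletic")
  expect_setequal(v$witness, c("A", "B", "C", "D"))
  expect_error(monophyly_status(tr, LETTERS[1:6]), "proper subset")
  expect_error(monophyly_status(tr, character(0)), "non-empty")
  expect_error(monophyly_status(ape::unroot(tr), c("A", "B")), "rooted")
})

test_that("monophyly verdicts ignore leaf order and out-of-clade additions", {
  tr <- ape::read.tree(text = "(((A,B),(C,D)),(E,F));")
  g <- c("C", "A", "B", "D")
  expect_equal(monophyly_status(tr, g)$status,
               monophyly_status(tr, rev(g))$status)
  # adding taxa outside the group's MRCA clade cannot change the verdict
  big <- ape::read.tree(text = "((((A,B),(C,D)),(E,F)),(G,H));")
  expect_equal(monophyly_status(big, c("A", "B", "C", "D"))$status,
               monophyly_status(tr, c("A", "B", "C", "D"))$status)
})

test_that("the classification universe excludes unlabelled lineages", {
  # archaic-like leaf X breaks complement-monophyly unless excluded
  tr <- ape::read.tree(text = "(O,(X,((M,S),(Y,L))));")
  expect_equal(monophyly_status(tr, c("M", "S", "Y"),
                                within = c("M", "S", "Y", "L"))$status,
               "paraphyletic")
  expect_equal(monophyly_status(tr, c("M", "S", "Y"),
                                outgroup = "O")$status, "polyphyletic")
})

test_that("attachment edges are recovered, with a flag on rearrangement", {
  prev <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  # graft X onto C's pendant edge
  curr <- ape::read.tree(text = "((A:1,B:1):1,((C:0.5,X:0.5):0.5,D:1):1);")
  att <- attachment_edge(prev, curr, "X")
  expect_equal(att$edge, "C")
  expect_false(att$shifted)
  expect_equal(att$sibling, "C")
  # graft onto an internal edge
  curr2 <- ape::read.tree(
    text = "((A:1,B:1):1,((C:1,D:1):0.5,X:0.5):0.5);")
  att2 <- attachment_edge(prev, curr2, "X")
  expect_equal(att2$edge, "C|D")
  expect_false(att2$shifted)
  # an extra rearrangement (A,B swapped with C) must raise the flag
  curr3 <- ape::read.tree(
    text = "((A:1,C:1):1,((B:1,D:1):0.5,X:0.5):0.5);")
  att3 <- attachment_edge(prev, curr3, "X")
  expect_true(att3$shifted)
  expect_error(attachment_edge(prev, curr, "Z"), "not a leaf")
  expect_error(attachment_edge(curr2, curr3, "X"), "plus the added taxon")
})

test_that("a taxon with an identical sequence attaches at that leaf's pendant edge", {
  aln <- preset_replicate(21, seq_length = 2000)
  m <- aln_matrix(aln)
  aln2 <- dna_alignment(rbind(m, Mbuti2 = m["Mbuti", ]))
  res <- ppa_run(aln2,
                 core = c("Pan", "Hsnd", "SH_Hsnn", "Hsnn_star", "Mbuti",
                          "Lund"),
                 additions = "Mbuti2", outgroup = "Pan",
                 groups = list(african = c("Mbuti", "Mbuti2"),
                               non_african = "Lund"))
  expect_equal(res$records[[1]]$attachment$edge, "Mbuti")
})

test_that("PPA on the preset replays the taxon-addition narrative", {
  spec <- build_scenario_preset("fig1_fig3")
  aln <- preset_replicate(31)
  groups <- split(spec$taxa$name, spec$taxa$group)
  groups <- groups[c("african", "non_african")]
  res <- ppa_run(aln, spec$ppa$core, spec$ppa$additions, outgroup = "Pan",
                 groups = groups)
  steps <- summary(res)
  expect_equal(steps$taxon, c("San", "Yoruba1", "Yoruba2", "French"))
  # San joins Mbuti; the Yorubas land on the non-African (Lund) side
  expect_equal(steps$edge[1], "Mbuti")
  expect_true(all(grepl("Lund", steps$edge[2:3])))
  # final verdicts: African paraphyletic, non-African monophyletic
  fin <- res$records[[length(res$records)]]$status
  expect_equal(fin$african$status, "paraphyletic")
  expect_equal(fin$non_african$status, "monophyletic")
  # full-rebuild semantics: final tree equals the one-shot inference
  oneshot <- root_with_outgroup(
    neighbor_joining(distance_matrix(aln, "K2P")), "Pan")
  expect_equal(compare_topologies(res$final_tree, oneshot)$rf_distance, 0)
})

test_that("parsimony PPA is capped at the enumeration limit", {
  aln <- preset_replicate(41, seq_length = 200)
  spec <- build_scenario_preset("fig1_fig3")
  expect_error(
    ppa_run(aln, spec$ppa$core, spec$ppa$additions, method = "parsimony",
            outgroup = "Pan", groups = list(african = "Mbuti")),
    "NJ")
  # within the cap it runs and roots every step
  res <- ppa_run(aln, core = c("Pan", "Mbuti", "Lund"),
                 additions = c("San", "Yoruba1"), method = "parsimony",
                 outgroup = "Pan",
                 groups = list(african = c("Mbuti", "San", "Yoruba1"),
                               non_african = "Lund"))
  expect_length(res$records, 2)
  expect_true(ape::is.rooted(res$final_tree))
})
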