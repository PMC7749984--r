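test_that("bipartition comparison matches Robinson-Foulds accounting", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  expect_equal(compare_topologies(t1, t1)$rf_distance, 0)
  expect_length(compare_topologies(t1, t1)$conflicting$ref, 0)
  # one NNI on a quartet: RF distance 2
  q1 <- ape::read.tree(text = "((A,B),(C,D));")
  q2 <- ape::read.tree(text = "((A,C),(B,D));")
  cmp <- compare_topologies(q1, q2)
  expect_equal(cmp$rf_distance, 2)
  expect_equal(cmp$rf_distance,
               as.numeric(phangorn::RF.dist(ape::unroot(q1),
                                            ape::unroot(q2))))
  expect_error(compare_topologies(t1, ape::rtree(4)), "identical leaf sets")
  # randomized cross-check against phangorn's RF distance
  set.seed(77)
  for (i in 1:10) {
    a <- ape::rtree(7, tip.label = letters[1:7])
    b <- ape::rtree(7, tip.label = letters[1:7])
    expect_equal(compare_topologies(a, b)$rf_distance,
                 as.numeric(phangorn::RF.dist(a, b)))
  }
})

test_that("the species/mtDNA tree pair is reconciled by removing Hsnn_star", {
  spec <- build_scenario_preset("fig1_fig3")
  sp <- species_tree(spec)
  mt <- derive_locus_tree(spec, "mtDNA")
  expect_gt(compare_topologies(sp, mt)$rf_distance, 0)
  disp <- displaced_taxa(sp, mt)
  expect_true(disp$reconciled)
  expect_equal(disp$taxa, "Hsnn_star")
  expect_equal(disp$k, 1L)
  # agreement with a brute-force scan over single-leaf removals
  singles <- Filter(function(tx) {
    compare_topologies(ape::drop.tip(sp, tx),
                       ape::drop.tip(mt, tx))$rf_distance == 0
  }, sort(sp$tip.label))
  expect_equal(singles, "Hsnn_star")
})

test_that("identical trees have no displaced taxa; deep conflicts report irreconcilable", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  d0 <- displaced_taxa(t1, t1)
  expect_true(d0$reconciled)
  expect_length(d0$taxa, 0)
  # trees differing everywhere cannot be fixed by removing one leaf
  a <- ape::read.tree(text = "(((A,B),(C,D)),((E,F),(G,H)));")
  b <- ape::read.tree(text = "(((A,E),(C,G)),((B,F),(D,H)));")
  d1 <- displaced_taxa(a, b, max_k = 1)
  expect_false(d1$reconciled)
  expect_output(print(d1), "irreconcilable")
})

test_that("pruning the displaced set reconciles random single-leaf moves", {
  set.seed(303)
  for (i in 1:20) {
    ref <- ape::rtree(8, tip.label = LETTERS[1:8])
    leaf <- sample(LETTERS[1:8], 1)
    test <- move_one_leaf(ref, leaf)
    disp <- displaced_taxa(ref, test)
    expect_true(disp$reconciled)
    expect_equal(
      compare_topologies(ape::drop.tip(ref, disp$taxa),
                         ape::drop.tip(test, disp$taxa))$rf_distance, 0)
  }
})

test_that("the sister-group rule infers the introgression direction", {
  # forward: Hsnn_star displaced onto the Hss branch => Hss is the donor
  ref <- ape::read.tree(
    text = "(Pan,((Hss1,Hss2),(Hsnd,(SH_Hsnn,Hsnn_star))));")
  fwd <- ape::read.tree(
    text = "(Pan,(((Hss1,Hss2),Hsnn_star),(Hsnd,SH_Hsnn)));")
  call <- infer_introgression_direction(ref, fwd, "Hsnn_star")
  expect_equal(call$recipient, "Hsnn_star")
  expect_setequal(call$donor_tips, c("Hss1", "Hss2"))
  # reverse: Hss displaced into the Neanderthal clade, (Hss,Hsnn_star)
  # sister to SH_Hsnn => Hsnn_star is the donor
  ref2 <- ape::read.tree(text = "(Pan,(Hss,(Hsnd,(SH_Hsnn,Hsnn_star))));")
  rev2 <- ape::read.tree(text = "(Pan,(Hsnd,(SH_Hsnn,(Hsnn_star,Hss))));")
  call2 <- infer_introgression_direction(ref2, rev2, "Hss")
  expect_equal(call2$recipient, "Hss")
  expect_equal(call2$donor_tips, "Hsnn_star")
  # concordant trees: nothing to infer
  expect_error(infer_introgression_direction(ref, ref, "Hsnn_star"),
               "concordant")
  # a taxon whose sister group did not change is not displaced
  expect_error(infer_introgression_direction(ref, fwd, "Hss1"),
               "not displaced")
})

test_that("the preset discordance report names Hsnn_star and the Hss donor", {
  spec <- build_scenario_preset("fig1_fig3")
  rep <- discordance_report(species_tree(spec),
                            derive_locus_tree(spec, "mtDNA"))
  expect_equal(rep$displaced$taxa, "Hsnn_star")
  call <- rep$directions[["Hsnn_star"]]
  expect_s3_class(call, "direction_call")
  hss <- spec$taxa$name[spec$taxa$group %in% c("african", "non_african")]
  expect_setequal(call$donor_tips, hss)
})
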