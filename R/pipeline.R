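# End-to-end pipeline: simulate -> distances -> infer -> PPA -> date ->
# discordance, collected into a reproducible run report.

#' Write / read a dated tree as Newick plus an age sidecar table
#'
#' The Newick file carries the topology and branch lengths; node ages are
#' serialized to a tab-separated sidecar (\code{<path>.ages.tsv}) with
#' columns \code{node} (ape node number) and \code{age_ybp}.
#'
#' @param tree a dated rooted \code{phylo} (edge lengths in years).
#' @param path output Newick path.
#' @return \code{read_dated_tree} returns a dated \code{phylo};
#'   \code{write_dated_tree} returns \code{path} invisibly.
#' @export
write_dated_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  ages <- node_depths(tree)
  utils::write.table(
    data.frame(node = seq_along(ages), age_ybp = ages),
    file = paste0(path, ".ages.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(path)
}

#' @rdname write_dated_tree
#' @export
read_dated_tree <- function(path) {
  tree <- ape::read.tree(path)
  attr(tree, "dated") <- TRUE
  tree
}

#' Run the full scenario pipeline
#'
#' Executes all stages deterministically for a given seed: derive the locus
#' tree from the scenario, simulate a clock-evolved alignment on it, build
#' the distance matrix, infer and root the tree, date its nodes through the
#' scenario calibration, run the PPA taxon-addition analysis, and compare
#' the inferred locus tree against the species tree to detect displaced
#' taxa and call the introgression direction.
#'
#' @param spec a [scenario_spec()] or the name of a preset (see
#'   [build_scenario_preset()]).
#' @param seed integer seed governing all randomness of the run.
#' @param locus which locus' tree to simulate (default \code{"mtDNA"}).
#' @param method tree-inference backend for the main tree and the PPA
#'   steps (\code{"NJ"} or \code{"parsimony"}).
#' @param dist_model distance model for NJ.
#' @param max_k displaced-set search cap for the discordance stage.
#' @return an object of class \code{scenario_run}; see the print method
#'   for the report layout. Key elements: \code{alignment}, \code{dist},
#'   \code{tree} (rooted inferred tree), \code{ages}, \code{date_chain}
#'   (one row per internal node of the true locus tree: leaf set, true age,
#'   estimated age), \code{ppa}, \code{discordance}.
#' @examples
#' run <- run_scenario("fig1_fig3", seed = 1)
#' run$date_chain
#' @export
run_scenario <- function(spec = "fig1_fig3", seed = 1L, locus = "mtDNA",
                         method = "NJ", dist_model = "K2P", max_k = 3) {
  if (is.character(spec)) spec <- build_scenario_preset(spec)
  stopifnot(inherits(spec, "scenario_spec"))
  sp_tree <- species_tree(spec)
  locus_tree <- derive_locus_tree(spec, locus)
  aln <- simulate_alignment(locus_tree, spec, seed = seed)
  D <- distance_matrix(aln, dist_model)
  inferred <- root_with_outgroup(neighbor_joining(D), spec$outgroup)
  ages <- calibrate_ages(inferred, spec$calibration$tips,
                         spec$calibration$age)
  date_chain <- chain_table(locus_tree, ages)
  groups <- split(spec$taxa$name, spec$taxa$group)
  groups <- groups[intersect(c("african", "non_african"), names(groups))]
  ppa <- ppa_run(aln, spec$ppa$core, spec$ppa$additions, method = method,
                 outgroup = spec$outgroup, groups = groups,
                 dist_model = dist_model)
  disc <- discordance_report(sp_tree, inferred, max_k = max_k)
  structure(list(spec = spec, seed = as.integer(seed), locus = locus,
                 method = method, dist_model = dist_model,
                 species_tree = sp_tree, locus_tree = locus_tree,
                 alignment = aln, dist = D, tree = inferred, ages = ages,
                 date_chain = date_chain, ppa = ppa, discordance = disc),
            class = "scenario_run")
}

# One row per internal node of the true dated locus tree: its leaf set,
# generating age, and the estimated age of the MRCA of that leaf set in
# the dated inferred tree.
chain_table <- function(locus_tree, ages) {
  true_ages <- node_depths(locus_tree)
  ntip <- length(locus_tree$tip.label)
  nodes <- ntip + seq_len(locus_tree$Nnode)
  clades <- lapply(nodes, function(v) sort(tips_under(locus_tree, v)))
  df <- data.frame(
    clade = vapply(clades, paste, character(1), collapse = "|"),
    n_tips = lengths(clades),
    true_age = unname(true_ages[nodes]),
    est_age = vapply(clades, function(tp) mrca_age(ages, tp), numeric(1)),
    stringsAsFactors = FALSE)
  df$est_rounded <- round_age(df$est_age)
  df[order(-df$true_age), ]
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("Scenario run: %s, locus %s, seed %d (%s/%s, %d sites)\n",
              x$spec$name, x$locus, x$seed, x$method, x$dist_model,
              aln_length(x$alignment)))
  cat(sprintf("Calibration: MRCA(%s) = %s YBP\n",
              paste(x$spec$calibration$tips, collapse = ", "),
              format(x$spec$calibration$age, big.mark = ",", scientific = FALSE)))
  cat("\nDate chain (true vs estimated, rounded to 25,000 yr):\n")
  dc <- x$date_chain
  for (i in seq_len(nrow(dc)))
    cat(sprintf("  %12s  ~%-12s {%s}\n",
                format(dc$true_age[i], big.mark = ",", scientific = FALSE),
                format(dc$est_rounded[i], big.mark = ",", scientific = FALSE), dc$clade[i]))
  cat("\n")
  print(x$ppa)
  cat("\n")
  print(x$discordance)
  invisible(x)
}

#' Write all artifacts of a scenario run to a directory
#'
#' Writes the simulated alignment (FASTA), the dated species and locus
#' trees and the inferred tree (Newick, with age sidecars for dated
#' trees), the distance matrix (PHYLIP square), the date chain and PPA
#' placements (TSV) and a plain-text summary. Output is a pure function of
#' the run object, so two runs with the same seed produce byte-identical
#' files.
#'
#' @param run a \code{scenario_run}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_fasta(run$alignment, fp("alignment.fasta"))
  write_dated_tree(run$species_tree, fp("species_tree.nwk"))
  write_dated_tree(run$locus_tree, fp(paste0(run$locus, "_tree.nwk")))
  ape::write.tree(run$tree, fp("inferred_tree.nwk"))
  write_phylip_dist(run$dist, fp("distances.phy"))
  utils::write.table(run$date_chain, fp("date_chain.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(summary(run$ppa), fp("ppa_placements.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(utils::capture.output(print(run)), fp("summary.txt"))
  invisible(dir)
}
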