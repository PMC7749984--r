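#' Scenario specifications for dated-tree sequence simulation
#'
#' A scenario specification bundles everything needed to generate synthetic
#' mtDNA-like data: a dated species tree (node ages in years before present,
#' YBP), a taxon table assigning each leaf to a group (african, non_african,
#' archaic, outgroup), a list of lineage-capture introgression events, and
#' strict-clock substitution-model parameters.
#'
#' The species tree is stored as a node table: one row per node with columns
#' \code{id}, \code{parent} (\code{NA} for the root), \code{age} (YBP) and
#' \code{label} (\code{NA} for internal nodes). Ages must strictly decrease
#' from root to leaves, and every introgression event must be younger than
#' the divergence of its donor and recipient lineages.
#'
#' @param taxa data frame with columns \code{name} and \code{group}; groups
#'   must be among \code{african}, \code{non_african}, \code{archaic},
#'   \code{outgroup}.
#' @param tree_table node table describing the dated species tree (see
#'   Details).
#' @param events data frame of introgression events with columns
#'   \code{donor}, \code{recipient} (leaf names whose ancestral lineages at
#'   the event age are the donor/recipient), \code{age} (YBP) and
#'   \code{locus}. May have zero rows.
#' @param clock_rate substitutions per site per year (strict clock).
#' @param seq_length number of sites to simulate.
#' @param model substitution model, \code{"JC69"} or \code{"K2P"}.
#' @param kappa transition/transversion rate ratio for K2P (ignored for
#'   JC69, where it is fixed at 1).
#' @param seed default RNG seed used by [simulate_alignment()] when no seed
#'   is given explicitly.
#' @param outgroup name of the outgroup leaf used for rooting.
#' @param calibration list with elements \code{tips} (a leaf pair whose MRCA
#'   is the calibration node) and \code{age} (its age in YBP).
#' @param ppa list with elements \code{core} and \code{additions}: the
#'   taxon sets driving [ppa_run()] in [run_scenario()].
#' @param name optional scenario name.
#' @param validate if \code{FALSE}, skip invariant checks (useful to
#'   construct deliberately invalid scenarios in tests).
#' @return an object of class \code{scenario_spec}.
#' @seealso [build_scenario_preset()], [species_tree()],
#'   [derive_locus_tree()], [simulate_alignment()]
#' @export
scenario_spec <- function(taxa, tree_table, events = NULL,
                          clock_rate = 1.5e-8, seq_length = 16500L,
                          model = c("K2P", "JC69"), kappa = 4,
                          seed = 1L, outgroup = NULL,
                          calibration = NULL, ppa = NULL,
                          name = "custom", validate = TRUE) {
  model <- match.arg(model)
  if (is.null(events)) {
    events <- data.frame(donor = character(0), recipient = character(0),
                         age = numeric(0), locus = character(0),
                         stringsAsFactors = FALSE)
  }
  spec <- structure(
    list(name = name, taxa = taxa, tree_table = tree_table, events = events,
         clock_rate = clock_rate, seq_length = as.integer(seq_length),
         model = model, kappa = if (model == "JC69") 1 else kappa,
         seed = as.integer(seed), outgroup = outgroup,
         calibration = calibration, ppa = ppa),
    class = "scenario_spec")
  if (validate) validate_scenario(spec)
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario specification:", x$name, "\n")
  cat(sprintf("  %d taxa (%s)\n", nrow(x$taxa),
              paste(sprintf("%s: %d", names(table(x$taxa$group)),
                            table(x$taxa$group)), collapse = ", ")))
  cat(sprintf("  model %s (kappa = %g), clock %.3g subs/site/yr, %d sites\n",
              x$model, x$kappa, x$clock_rate, x$seq_length))
  if (nrow(x$events)) {
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("  event: %s -> %s at %s YBP (locus %s)\n",
                  x$events$donor[i], x$events$recipient[i],
                  format(x$events$age[i], big.mark = ",", scientific = FALSE),
                  x$events$locus[i]))
  } else cat("  no introgression events\n")
  invisible(x)
}

# Check all scenario_spec invariants; stop() on the first violation.
validate_scenario <- function(spec) {
  nt <- spec$tree_table
  stopifnot(is.data.frame(nt), all(c("id", "parent", "age", "label") %in%
                                     names(nt)))
  if (spec$clock_rate < 0) stop("clock_rate must be >= 0")
  if (spec$seq_length <= 0) stop("seq_length must be > 0")
  if (spec$kappa <= 0) stop("kappa must be > 0")
  root <- nt$id[is.na(nt$parent)]
  if (length(root) != 1) stop("tree must have exactly one root")
  # ages strictly decrease root -> leaf
  has_parent <- !is.na(nt$parent)
  page <- nt$age[match(nt$parent[has_parent], nt$id)]
  if (!all(page > nt$age[has_parent]))
    stop("node ages must strictly decrease from root to leaves")
  leaves <- nt$label[!is.na(nt$label)]
  if (anyDuplicated(leaves)) stop("leaf labels must be unique")
  if (!setequal(leaves, spec$taxa$name))
    stop("tree leaves must match the taxon table")
  bad <- setdiff(spec$taxa$group,
                 c("african", "non_african", "archaic", "outgroup"))
  if (length(bad)) stop("unknown taxon group(s): ", paste(bad, collapse = ", "))
  ev <- spec$events
  for (i in seq_len(nrow(ev))) {
    for (who in c("donor", "recipient"))
      if (!ev[[who]][i] %in% leaves)
        stop("event ", i, ": unknown ", who, " '", ev[[who]][i], "'")
    div <- nt_mrca_age(nt, ev$donor[i], ev$recipient[i])
    if (ev$age[i] >= div)
      stop("event ", i, ": age ", ev$age[i],
           " is not younger than the donor/recipient divergence (", div, ")")
    if (ev$age[i] <= 0) stop("event ", i, ": age must be positive")
  }
  invisible(spec)
}

# Age of the MRCA of two leaves in a node table.
nt_mrca_age <- function(nt, a, b) {
  anc <- function(label) {
    id <- nt$id[match(label, nt$label)]
    path <- id
    while (!is.na(nt$parent[match(id, nt$id)])) {
      id <- nt$parent[match(id, nt$id)]
      path <- c(path, id)
    }
    path
  }
  common <- intersect(anc(a), anc(b))
  min(nt$age[match(common, nt$id)])
}

# Build a node table from a nested list: internal nodes are
# list(age = , children = list(...)), leaves are character names of age 0.
nested_to_table <- function(x) {
  rows <- list()
  nid <- 0L
  rec <- function(node, parent) {
    nid <<- nid + 1L
    me <- nid
    if (is.character(node)) {
      rows[[me]] <<- data.frame(id = me, parent = parent, age = 0,
                                label = node, stringsAsFactors = FALSE)
    } else {
      rows[[me]] <<- data.frame(id = me, parent = parent, age = node$age,
                                label = NA_character_,
                                stringsAsFactors = FALSE)
      for (ch in node$children) rec(ch, me)
    }
  }
  rec(x, NA_integer_)
  do.call(rbind, rows)
}

#' Built-in scenario presets
#'
#' \code{"fig1_fig3"} encodes the hominin mtDNA scenario the package is
#' organised around: a Pan outgroup calibrated at a Pan/Homo divergence of
#' 8 MYBP; a basal split within Homo at 800,000 YBP separating the modern
#' human (Hss) lineage from the Neanderthal/Denisovan (Hsn) lineage; within
#' Hsn, a Denisovan (Hsnd) vs Neanderthal split at 700,000 YBP and a
#' Sima-de-los-Huesos (SH_Hsnn) vs main-Neanderthal (Hsnn_star) split at
#' 600,000 YBP; within Hss, a basal extant-human split at 250,000 YBP
#' (Mbuti/San vs all others), Yoruba divergences at 225,000 and 180,000 YBP
#' along the non-African stem, and a basal non-African split (Lund vs
#' French) at 125,000 YBP. A single mtDNA lineage-capture introgression from
#' the Hss stem into Hsnn_star is placed at 500,000 YBP, making the mtDNA
#' locus tree discordant with the species tree.
#'
#' @param name preset name; currently only \code{"fig1_fig3"}.
#' @return a [scenario_spec()] object (deterministic for a given name).
#' @examples
#' spec <- build_scenario_preset("fig1_fig3")
#' spec$events
#' @export
build_scenario_preset <- function(name = "fig1_fig3") {
  if (!identical(name, "fig1_fig3"))
    stop("unknown preset '", name, "'; available: fig1_fig3")
  taxa <- data.frame(
    name  = c("Pan", "Hsnd", "SH_Hsnn", "Hsnn_star",
              "Mbuti", "San", "Yoruba1", "Yoruba2", "Lund", "French"),
    group = c("outgroup", "archaic", "archaic", "archaic",
              "african", "african", "african", "african",
              "non_african", "non_african"),
    stringsAsFactors = FALSE)
  tree <- list(age = 8e6, children = list(
    "Pan",
    list(age = 8e5, children = list(
      list(age = 2.5e5, children = list(
        list(age = 2.0e5, children = list("Mbuti", "San")),
        list(age = 2.25e5, children = list(
          "Yoruba1",
          list(age = 1.8e5, children = list(
            "Yoruba2",
            list(age = 1.25e5, children = list("Lund", "French"))))))
      )),
      list(age = 7e5, children = list(
        "Hsnd",
        list(age = 6e5, children = list("SH_Hsnn", "Hsnn_star"))))
    ))))
  events <- data.frame(donor = "Mbuti", recipient = "Hsnn_star",
                       age = 5e5, locus = "mtDNA", stringsAsFactors = FALSE)
  scenario_spec(
    taxa = taxa, tree_table = nested_to_table(tree), events = events,
    clock_rate = 1.5e-8, seq_length = 16500L, model = "K2P", kappa = 4,
    seed = 1L, outgroup = "Pan",
    calibration = list(tips = c("Pan", "Mbuti"), age = 8e6),
    ppa = list(core = c("Pan", "Hsnd", "SH_Hsnn", "Hsnn_star",
                        "Mbuti", "Lund"),
               additions = c("San", "Yoruba1", "Yoruba2", "French")),
    name = "fig1_fig3")
}

# Convert a node table to a dated ape::phylo (edge lengths in years).
nt_to_phylo <- function(nt, tip_order = NULL) {
  leaves <- nt[!is.na(nt$label), ]
  if (is.null(tip_order)) tip_order <- leaves$label
  ntip <- nrow(leaves)
  internal <- nt$id[is.na(nt$label)]
  root <- nt$id[is.na(nt$parent)]
  # preorder numbering of internal nodes so that root == ntip + 1
  kids <- split(nt$id, factor(nt$parent, levels = nt$id))
  ord <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    if (v %in% internal) {
      ord <- c(ord, v)
      stack <- c(kids[[as.character(v)]], stack)
    }
  }
  num <- integer(max(nt$id))
  num[leaves$id] <- match(leaves$label, tip_order)
  num[ord] <- ntip + seq_along(ord)
  has_parent <- !is.na(nt$parent)
  edge <- cbind(num[nt$parent[has_parent]], num[nt$id[has_parent]])
  len <- nt$age[match(nt$parent[has_parent], nt$id)] - nt$age[has_parent]
  phy <- list(edge = edge, edge.length = len, tip.label = tip_order,
              Nnode = length(ord))
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  attr(phy, "dated") <- TRUE
  phy
}

#' Dated species tree of a scenario
#'
#' @param spec a [scenario_spec()] object.
#' @return a rooted, ultrametric \code{phylo} with edge lengths in years and
#'   attribute \code{dated = TRUE}.
#' @export
species_tree <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  nt_to_phylo(spec$tree_table, tip_order = spec$taxa$name)
}

#' Derive the dated gene tree of a locus from a scenario
#'
#' Applies every introgression event registered for \code{locus} to the
#' species tree. An event is a full lineage capture: the recipient lineage
#' (the subtree hanging below the recipient's ancestral branch at the event
#' age) is detached and re-attached to the donor's ancestral branch at
#' exactly the event age, so the resulting tree is again dated and
#' ultrametric. With no events for the locus the species tree is returned
#' unchanged.
#'
#' @param spec a [scenario_spec()] object.
#' @param locus locus name; events with a matching \code{locus} field are
#'   applied (oldest first).
#' @return a dated, rooted, ultrametric \code{phylo} (edge lengths in
#'   years).
#' @examples
#' spec <- build_scenario_preset("fig1_fig3")
#' mt <- derive_locus_tree(spec, "mtDNA")
#' @export
derive_locus_tree <- function(spec, locus) {
  stopifnot(inherits(spec, "scenario_spec"))
  nt <- spec$tree_table
  ev <- spec$events[spec$events$locus == locus, , drop = FALSE]
  if (nrow(ev)) {
    ev <- ev[order(-ev$age), , drop = FALSE]
    for (i in seq_len(nrow(ev)))
      nt <- apply_capture_event(nt, ev$donor[i], ev$recipient[i], ev$age[i])
  }
  nt_to_phylo(nt, tip_order = intersect(spec$taxa$name,
                                        nt$label[!is.na(nt$label)]))
}

# Walk from a leaf toward the root; return c(child, parent) ids of the edge
# spanning `age` on that path.
nt_spanning_edge <- function(nt, leaf, age) {
  id <- nt$id[match(leaf, nt$label)]
  if (is.na(id)) stop("unknown leaf '", leaf, "'")
  repeat {
    p <- nt$parent[match(id, nt$id)]
    if (is.na(p))
      stop("event age ", age, " is older than the root for lineage '",
           leaf, "'")
    page <- nt$age[match(p, nt$id)]
    if (page > age) return(c(child = id, parent = p))
    if (page == age)
      stop("event age ", age, " coincides exactly with a divergence on the ",
           "lineage of '", leaf, "'")
    id <- p
  }
}

# One lineage-capture introgression on a node table.
apply_capture_event <- function(nt, donor, recipient, age) {
  div <- nt_mrca_age(nt, donor, recipient)
  if (age >= div)
    stop("introgression at ", age, " YBP predates the divergence (", div,
         " YBP) of donor '", donor, "' and recipient '", recipient, "'")
  rec <- nt_spanning_edge(nt, recipient, age)
  # detach the recipient subtree
  rp <- rec[["parent"]]; rv <- rec[["child"]]
  nt$parent[match(rv, nt$id)] <- NA_integer_
  sibs <- nt$id[!is.na(nt$parent) & nt$parent == rp]
  if (length(sibs) == 1) { # suppress the now-degree-2 node
    gp <- nt$parent[match(rp, nt$id)]
    nt$parent[match(sibs, nt$id)] <- gp      # may be NA: sib becomes root
    nt <- nt[nt$id != rp, ]
  }
  don <- nt_spanning_edge(nt, donor, age)
  new_id <- max(nt$id) + 1L
  nt <- rbind(nt, data.frame(id = new_id,
                             parent = don[["parent"]], age = age,
                             label = NA_character_, stringsAsFactors = FALSE))
  nt$parent[match(don[["child"]], nt$id)] <- new_id
  nt$parent[match(rv, nt$id)] <- new_id
  nt
}

#' Node ages of a dated tree
#'
#' For a dated ultrametric tree (edge lengths in years) this is simply the
#' distance from each node down to its leaves; see [node_depths()] for the
#' general (non-ultrametric) depth used in calibrated dating.
#'
#' @param phy a dated rooted \code{phylo}.
#' @return numeric vector of ages (YBP) indexed by ape node number.
#' @export
tree_ages <- function(phy) node_depths(phy)
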