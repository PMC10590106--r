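#' Configuration of the synthetic knowledge-graph generator
#'
#' The generator emulates the structure of a kinase-centric knowledge
#' graph at desk scale: proteins grouped into pathways, co-members sharing
#' annotation context (GO terms, domains, PTMs, chemicals, diseases) and
#' protein-protein interactions, a fraction of "dark" proteins whose direct
#' pathway edge is withheld (they keep context and PPI edges - the
#' sparsely annotated kinases the method targets), and a hub layer with
#' power-law degrees that exercises the inverse-degree walk bias.
#'
#' @param n_pathways number of pathways (default 3).
#' @param proteins_per_pathway proteins planted per pathway (default 30).
#' @param dark_fraction fraction of each pathway's proteins made dark
#'   (default 0.2); must leave at least one light protein per pathway.
#' @param context named integer vector: shared context nodes per pathway
#'   for each context type.
#' @param context_attach_prob probability a member protein links to each of
#'   its pathway's context nodes (each protein is guaranteed >= 1).
#' @param ppi_within_pathway_prob,ppi_noise_prob PPI probability for
#'   within-pathway and cross-pathway protein pairs.
#' @param n_hubs,hub_exponent decoy hub nodes and the exponent of their
#'   power-law degree distribution.
#' @param seed master seed (default 17).
#' @return list of class \code{"synthetic_kg_config"}.
#' @export
synthetic_kg_config <- function(n_pathways = 3L, proteins_per_pathway = 30L,
                                dark_fraction = 0.2,
                                context = c(MolecularFunction = 4L,
                                            BiologicalProcess = 4L,
                                            CellularComponent = 3L,
                                            FunctionalDomain = 3L,
                                            PTM = 2L, Chemical = 2L,
                                            Disease = 2L),
                                context_attach_prob = 0.5,
                                ppi_within_pathway_prob = 0.1,
                                ppi_noise_prob = 0.005,
                                n_hubs = 8L, hub_exponent = 2.5,
                                seed = 17L) {
  stopifnot(dark_fraction >= 0, dark_fraction < 1,
            context_attach_prob >= 0, context_attach_prob <= 1,
            ppi_within_pathway_prob >= 0, ppi_within_pathway_prob <= 1,
            ppi_noise_prob >= 0, ppi_noise_prob <= 1,
            all(context >= 0L), n_pathways >= 1L,
            proteins_per_pathway >= 1L)
  structure(list(n_pathways = as.integer(n_pathways),
                 proteins_per_pathway = as.integer(proteins_per_pathway),
                 dark_fraction = dark_fraction, context = context,
                 context_attach_prob = context_attach_prob,
                 ppi_within_pathway_prob = ppi_within_pathway_prob,
                 ppi_noise_prob = ppi_noise_prob,
                 n_hubs = as.integer(n_hubs), hub_exponent = hub_exponent,
                 seed = as.integer(seed)),
            class = "synthetic_kg_config")
}

context_relation <- c(MolecularFunction = "hasMolecularFunction",
                      BiologicalProcess = "hasBiologicalProcess",
                      CellularComponent = "hasCellularComponent",
                      FunctionalDomain = "hasDomain",
                      PTM = "hasPTM",
                      Chemical = "associatedWithChemical",
                      Disease = "associatedWithDisease")

#' Generate a seeded synthetic knowledge graph with planted structure
#'
#' @param config a [synthetic_kg_config()].
#' @return list with \code{graph} (a \code{"kg"} with DarkKinase /
#'   LightKinase subtyped under Protein) and \code{truth}, a data.frame of
#'   the planted protein -> pathway memberships with a \code{dark} flag
#'   (dark memberships are absent from the emitted graph).
#' @export
generate_synthetic_kg <- function(config = synthetic_kg_config()) {
  stopifnot(inherits(config, "synthetic_kg_config"))
  set.seed(config$seed)
  K <- config$n_pathways; m <- config$proteins_per_pathway
  n_dark <- round(config$dark_fraction * m)
  if (n_dark >= m)
    stop("infeasible config: dark_fraction leaves no light protein to ",
         "anchor a pathway")

  pathways <- sprintf("path%02d", seq_len(K))
  prot <- sprintf("P%03d", seq_len(K * m))
  prot_path <- rep(seq_len(K), each = m)

  # dark members per pathway (seeded), remaining light alternate between
  # the LightKinase subtype and the plain Protein type
  dark <- logical(K * m)
  for (k in seq_len(K)) {
    members <- which(prot_path == k)
    dark[sample(members, n_dark)] <- TRUE
  }
  ptype <- character(K * m)
  ptype[dark] <- "DarkKinase"
  light_idx <- which(!dark)
  ptype[light_idx] <- rep_len(c("LightKinase", "Protein"),
                              length(light_idx))

  nodes <- c(stats::setNames(ptype, prot),
             stats::setNames(rep("Pathway", K), pathways))
  edges <- list()
  add_edges <- function(h, r, t) {
    edges[[length(edges) + 1L]] <<- data.frame(head = h, relation = r,
                                               tail = t,
                                               stringsAsFactors = FALSE)
  }

  # shared context nodes per pathway
  for (k in seq_len(K)) {
    members <- prot[prot_path == k]
    attached <- stats::setNames(rep(FALSE, length(members)), members)
    for (ct in names(config$context)) {
      nct <- config$context[[ct]]
      if (nct == 0L) next
      ids <- sprintf("%s%02d_%02d", tolower(substr(ct, 1L, 2L)), k,
                     seq_len(nct))
      nodes <- c(nodes, stats::setNames(rep(ct, nct), ids))
      for (p in members) {
        link <- stats::runif(nct) < config$context_attach_prob
        if (any(link)) {
          add_edges(p, context_relation[[ct]], ids[link])
          attached[[p]] <- TRUE
        }
      }
    }
    # every protein keeps at least one context edge (dark ones especially:
    # context is all they have)
    for (p in members[!attached]) {
      ct <- names(config$context)[config$context > 0L][1L]
      add_edges(p, context_relation[[ct]],
                sprintf("%s%02d_%02d", tolower(substr(ct, 1L, 2L)), k, 1L))
    }
  }

  # pathway membership, withheld for dark proteins
  light_members <- which(!dark)
  add_edges(prot[light_members], "hasPathway",
            pathways[prot_path[light_members]])

  # protein-protein interactions: dense within a pathway, sparse across
  pairs <- utils::combn(seq_len(K * m), 2L)
  same <- prot_path[pairs[1L, ]] == prot_path[pairs[2L, ]]
  pp <- ifelse(same, config$ppi_within_pathway_prob, config$ppi_noise_prob)
  keep <- stats::runif(ncol(pairs)) < pp
  if (any(keep))
    add_edges(prot[pairs[1L, keep]], "interactsWith", prot[pairs[2L, keep]])

  # decoy hubs with power-law degrees
  if (config$n_hubs > 0L) {
    hub_type <- rep_len(c("Chemical", "Disease"), config$n_hubs)
    hub_ids <- sprintf("hub%02d", seq_len(config$n_hubs))
    nodes <- c(nodes, stats::setNames(hub_type, hub_ids))
    for (h in seq_len(config$n_hubs)) {
      u <- stats::runif(1L)
      deg <- min(K * m, max(3L, round(3 * u^(-1 / (config$hub_exponent - 1)))))
      tgt <- sample(prot, deg)
      add_edges(hub_ids[[h]], context_relation[[hub_type[[h]]]], tgt)
    }
  }

  graph <- kg(nodes = nodes, edges = do.call(rbind, edges),
              hierarchy = c(DarkKinase = "Protein",
                            LightKinase = "Protein"))
  truth <- data.frame(protein = prot, pathway = pathways[prot_path],
                      dark = dark, stringsAsFactors = FALSE)
  list(graph = graph, truth = truth, config = config)
}

#' Emit raw source-style association tables with filter boundary cases
#'
#' Produces the simplified per-source tables the curation filters consume,
#' constructed so every rule has rows on both sides of its threshold:
#' evidence codes TAS and IEA, experimental scores 650/700/701, PTM
#' confidences 0.9/1.0/1.5, one annotation term just over and one at the
#' association cap, and kinase-domain rows among ordinary domains.
#'
#' @param config a [synthetic_kg_config()] (its seed drives the random
#'   rows).
#' @param go_cap the association cap the emitted term table straddles
#'   (default 50; the full-scale rule uses 5000).
#' @return named list of data.frames: \code{reactome},
#'   \code{reactome_hierarchy}, \code{go}, \code{string}, \code{iptmnet},
#'   \code{pfam}.
#' @export
emit_source_tables <- function(config = synthetic_kg_config(),
                               go_cap = 50L) {
  set.seed(config$seed + 1L)
  prot <- sprintf("P%03d", seq_len(config$n_pathways *
                                   config$proteins_per_pathway))
  n <- length(prot)

  reactome <- data.frame(
    protein = rep(prot[seq_len(min(n, 12L))], each = 2L),
    pathway = rep(c("R-HSA-0001", "R-HSA-0002"), min(n, 12L)),
    evidence = rep_len(c("TAS", "IEA"), 2L * min(n, 12L)),
    stringsAsFactors = FALSE)
  extra <- data.frame(protein = prot[1:4],
                      pathway = c("R-HSA-DIS1", "R-HSA-DIS2",
                                  "R-HSA-INF1", "R-HSA-0003"),
                      evidence = "TAS", stringsAsFactors = FALSE)
  reactome <- rbind(reactome, extra)

  reactome_hierarchy <- data.frame(
    child = c("R-HSA-5663205", "R-HSA-DIS1", "R-HSA-DIS2", "R-HSA-INF1",
              "R-HSA-0001"),
    parent = c("R-HSA-1643685", "R-HSA-1643685", "R-HSA-DIS1",
               "R-HSA-5663205", "R-HSA-ROOT"),
    stringsAsFactors = FALSE)

  big_term <- data.frame(protein = sample(prot, go_cap + 1L, replace = TRUE),
                         go_term = "GO:BIG",
                         namespace = "BiologicalProcess",
                         stringsAsFactors = FALSE)
  ok_term <- data.frame(protein = sample(prot, go_cap, replace = TRUE),
                        go_term = "GO:ATCAP",
                        namespace = "MolecularFunction",
                        stringsAsFactors = FALSE)
  small_terms <- data.frame(protein = sample(prot, 20L, replace = TRUE),
                            go_term = sample(sprintf("GO:%04d", 1:5), 20L,
                                             replace = TRUE),
                            namespace = "CellularComponent",
                            stringsAsFactors = FALSE)
  go <- rbind(big_term, ok_term, small_terms)

  string <- data.frame(
    protein1 = c(prot[1L], prot[2L], prot[3L], prot[4L], "Q_nonkin1"),
    protein2 = c(prot[5L], prot[6L], prot[7L], "Q_nonkin2", "Q_nonkin2"),
    experimental_score = c(650, 700, 701, 900, 900),
    stringsAsFactors = FALSE)
  more <- data.frame(protein1 = sample(prot, 15L, replace = TRUE),
                     protein2 = sample(prot, 15L, replace = TRUE),
                     experimental_score = round(stats::runif(15L, 400, 999)),
                     stringsAsFactors = FALSE)
  string <- rbind(string, more[more$protein1 != more$protein2, ,
                               drop = FALSE])

  iptmnet <- data.frame(
    enzyme = prot[c(1L, 2L, 3L, sample(n, 10L))],
    substrate = prot[c(5L, 6L, 7L, sample(n, 10L))],
    confidence = c(0.9, 1.0, 1.5, round(stats::runif(10L, 0, 3), 2L)),
    stringsAsFactors = FALSE)

  pfam <- data.frame(
    protein = prot[rep_len(1:10, 14L)],
    domain = c("Pkinase", "Pkinase_Tyr", "SH2", "SH3", "PH",
               sample(c("Pkinase", "SH2", "WD40", "RING"), 9L,
                      replace = TRUE)),
    stringsAsFactors = FALSE)

  lapply(list(reactome = reactome,
              reactome_hierarchy = reactome_hierarchy, go = go,
              string = string, iptmnet = iptmnet, pfam = pfam),
         function(d) { row.names(d) <- NULL; d })
}
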