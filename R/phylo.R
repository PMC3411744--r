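#' @include genome.R
NULL

.mp_new <- function(label, parent, haplogroup, mutations, genome = NULL) {
  keys <- lapply(mutations, function(ms) {
    if (!length(ms)) return(character(0))
    vapply(parseVariantLabels(ms, genome), variantKey, character(1))
  })
  new("MitoPhylo", label = label, parent = as.integer(parent),
      haplogroup = haplogroup, mutations = mutations, mutationKeys = keys)
}

.mp_children <- function(phylo, i) which(phylo@parent == i)

.mp_root <- function(phylo) which(is.na(phylo@parent))

.mp_leaves <- function(phylo)
  setdiff(seq_along(phylo@label), unique(phylo@parent[!is.na(phylo@parent)]))

.mp_depth <- function(phylo, i) {
  d <- 0L
  while (!is.na(phylo@parent[i])) { i <- phylo@parent[i]; d <- d + 1L }
  d
}

.mp_path <- function(phylo, i) {  # root .. i
  p <- i
  while (!is.na(phylo@parent[i])) { i <- phylo@parent[i]; p <- c(i, p) }
  p
}

# expected mutation keys accumulated along the root-to-node path; a reversion
# key "@<key>" removes any previously expected mutation at its position
.mp_expected <- function(phylo, node) {
  exp <- character(0)
  for (i in .mp_path(phylo, node)) {
    for (k in phylo@mutationKeys[[i]]) {
      if (startsWith(k, "@")) {
        pos <- sub(":.*$", "", substring(k, 2L))
        exp <- exp[sub(":.*$", "", exp) != pos]
      } else exp <- union(exp, k)
    }
  }
  exp
}

#' Leaf labels of a phylogeny
#' @param phylo a [MitoPhylo-class].
#' @export
leafLabels <- function(phylo) phylo@label[.mp_leaves(phylo)]

#' Haplogroup labels present in a phylogeny
#' @param phylo a [MitoPhylo-class].
#' @export
haplogroupLabels <- function(phylo) phylo@haplogroup[!is.na(phylo@haplogroup)]

#' Parse a reference phylogeny
#'
#' Two tree dialects are read, auto-detected:
#'
#' **Indented text** (the packaged cohort fixture): one node per line,
#' depth given by leading spaces (2 per level), fields separated by `;`.  The
#' first field is the node name; optional `hg=<name>` attaches a haplogroup
#' and `muts=<a>,<b>,...` lists the mutations of the incoming branch in the
#' shorthand dialect.  Lines starting with `#` are comments.
#'
#' **Annotated Newick**: node annotations in bracketed comments after the node
#' label, e.g. `(F1[&muts={3700,13759}],H26a[&hg=H26a])H[&hg=H];`.  Branch
#' lengths (`:x`) are accepted and ignored.
#'
#' @param x path to a file, or the document itself (character scalar with
#'   newlines, or a character vector of lines).
#' @param genome optional [MitoGenome-class]; when supplied, branch mutations
#'   are resolved against it so motif matching uses fully resolved keys.
#' @return a [MitoPhylo-class].
#' @export
parsePhylogeny <- function(x, genome = NULL) {
  if (length(x) == 1L && !grepl("\n", x) && !grepl("[();]", x) &&
      file.exists(x))
    x <- readLines(x, warn = FALSE)
  else if (length(x) == 1L && grepl("\n", x))
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  body <- x[!grepl("^\\s*(#|$)", x)]
  if (!length(body)) stop("empty tree document")
  if (grepl("^\\s*\\(", body[1]))
    .parse_newick(paste(body, collapse = ""), genome)
  else
    .parse_indented(body, genome)
}

.parse_node_fields <- function(fields, line) {
  name <- trimws(fields[1])
  hg <- NA_character_; muts <- character(0)
  for (f in fields[-1]) {
    f <- trimws(f)
    if (f == "") next
    if (startsWith(f, "hg=")) hg <- substring(f, 4L)
    else if (startsWith(f, "muts=")) {
      v <- trimws(strsplit(substring(f, 6L), ",")[[1]])
      muts <- v[v != ""]
    }
    else stop("line ", line, ": unknown field '", f, "'")
  }
  list(name = name, hg = hg, muts = muts)
}

.parse_indented <- function(lines, genome) {
  label <- character(0); parent <- integer(0)
  hg <- character(0); muts <- list()
  stack <- integer(0)  # node index at each depth
  for (li in seq_along(lines)) {
    line <- lines[li]
    indent <- nchar(line) - nchar(sub("^ *", "", line))
    if (indent %% 2L != 0L)
      stop("line ", li, ": indentation must be a multiple of 2 spaces")
    depth <- indent %/% 2L
    if (depth > length(stack))
      stop("line ", li, ": indentation jumps more than one level")
    f <- .parse_node_fields(strsplit(sub("^ *", "", line), ";")[[1]], li)
    idx <- length(label) + 1L
    label <- c(label, f$name)
    parent <- c(parent, if (depth == 0L) NA_integer_ else stack[depth])
    hg <- c(hg, f$hg)
    muts[[idx]] <- f$muts
    stack <- c(stack[seq_len(depth)], idx)
  }
  if (sum(is.na(parent)) != 1L)
    stop("indented tree must have exactly one root line at depth 0")
  .mp_new(label, parent, hg, muts, genome)
}

# recursive-descent Newick with [&hg=...,muts={...}] annotations
.parse_newick <- function(txt, genome) {
  txt <- sub(";\\s*$", "", trimws(txt))
  label <- character(0); parent <- integer(0)
  hg <- character(0); muts <- list()
  i <- 1L
  n <- nchar(txt)
  peek <- function() if (i <= n) substr(txt, i, i) else ""
  adv <- function() i <<- i + 1L

  read_annot <- function() {
    out <- list(hg = NA_character_, muts = character(0))
    if (peek() != "[") return(out)
    j <- regexpr("\\]", substring(txt, i))
    if (j < 0) stop("unterminated annotation at character ", i)
    ann <- substring(txt, i + 1L, i + j - 2L)
    i <<- i + j
    ann <- sub("^&", "", ann)
    # split on commas outside braces
    parts <- regmatches(ann, gregexpr("[a-z]+=\\{[^}]*\\}|[a-z]+=[^,{}]*", ann))[[1]]
    for (p in parts) {
      kv <- sub("=.*$", "", p); val <- sub("^[a-z]+=", "", p)
      if (kv == "hg") out$hg <- val
      else if (kv == "muts") {
        val <- gsub("[{}]", "", val)
        v <- trimws(strsplit(val, ",")[[1]])
        out$muts <- v[v != ""]
      } else stop("unknown annotation key '", kv, "'")
    }
    out
  }

  read_label <- function() {
    m <- regexpr("^[^(),:;\\[\\]]+", substring(txt, i), perl = TRUE)
    if (m < 0) return("")
    lab <- regmatches(substring(txt, i), m)
    i <<- i + attr(m, "match.length")
    trimws(lab)
  }

  read_node <- function() {  # returns node index
    kids <- integer(0)
    if (peek() == "(") {
      adv()
      repeat {
        kids <- c(kids, read_node())
        if (peek() == ",") { adv(); next }
        if (peek() == ")") { adv(); break }
        stop("unbalanced parentheses near character ", i)
      }
    }
    lab <- read_label()
    ann <- read_annot()
    if (peek() == ":") {  # skip branch length
      adv()
      m <- regexpr("^[0-9.eE+-]+", substring(txt, i))
      if (m > 0) i <<- i + attr(m, "match.length")
    }
    idx <- length(label) + 1L
    label <<- c(label, if (lab == "") paste0("node", idx) else lab)
    parent <<- c(parent, NA_integer_)
    hg <<- c(hg, ann$hg)
    muts[[idx]] <<- ann$muts
    for (k in kids) parent[k] <<- idx
    idx
  }

  root <- read_node()
  if (i <= n) stop("trailing characters after tree near character ", i)
  # renumber nodes in pre-order so both dialects yield identical objects
  nn <- length(label)
  perm <- integer(nn); cnt <- 0L
  dfs <- function(v) {
    cnt <<- cnt + 1L; perm[v] <<- cnt
    for (k in which(parent == v)) dfs(k)
  }
  dfs(root)
  label2 <- character(nn); hg2 <- character(nn)
  parent2 <- integer(nn); muts2 <- vector("list", nn)
  label2[perm] <- label; hg2[perm] <- hg
  parent2[perm] <- ifelse(is.na(parent), NA_integer_, perm[parent])
  muts2[perm] <- muts
  .mp_new(label2, parent2, hg2, muts2, genome)
}

#' Serialise a phylogeny
#'
#' Writes the tree back in either dialect accepted by [parsePhylogeny()];
#' parse -> serialise -> parse is a fixpoint.
#'
#' @param phylo a [MitoPhylo-class].
#' @param format `"indented"` or `"newick"`.
#' @return character: lines (indented) or a single Newick string.
#' @export
serializePhylogeny <- function(phylo, format = c("indented", "newick")) {
  format <- match.arg(format)
  root <- .mp_root(phylo)
  if (format == "indented") {
    out <- character(0)
    rec <- function(i, depth) {
      f <- paste0(strrep("  ", depth), phylo@label[i])
      if (!is.na(phylo@haplogroup[i]))
        f <- paste0(f, " ; hg=", phylo@haplogroup[i])
      if (length(phylo@mutations[[i]]))
        f <- paste0(f, " ; muts=", paste(phylo@mutations[[i]], collapse = ","))
      out <<- c(out, f)
      for (k in .mp_children(phylo, i)) rec(k, depth + 1L)
    }
    rec(root, 0L)
    out
  } else {
    rec <- function(i) {
      kids <- .mp_children(phylo, i)
      ann <- character(0)
      if (!is.na(phylo@haplogroup[i]))
        ann <- c(ann, paste0("hg=", phylo@haplogroup[i]))
      if (length(phylo@mutations[[i]]))
        ann <- c(ann, paste0("muts={",
                             paste(phylo@mutations[[i]], collapse = ","), "}"))
      ann <- if (length(ann)) paste0("[&", paste(ann, collapse = ","), "]") else ""
      if (length(kids))
        paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
               ")", phylo@label[i], ann)
      else paste0(phylo@label[i], ann)
    }
    paste0(rec(root), ";")
  }
}

#' Assign a haplogroup by motif matching
#'
#' Scores every named haplogroup node by the mutational motif accumulated on
#' its root-to-node path: `score = matched - missing` expected mutations.
#' Private variants of the haplotype neither reward nor penalise.  Ties are
#' broken toward the less derived (shallower) node; all co-optimal nodes are
#' reported.
#'
#' @param haplotype a [HaplotypeProfile-class], or a list of
#'   [MitoVariant-class], or a character vector of labels (resolved against
#'   `genome` if given).
#' @param phylo a [MitoPhylo-class] with at least one named haplogroup node.
#' @param genome optional genome for resolving character labels.
#' @param missingWeight penalty weight for missing expected mutations.
#' @return list with `haplogroup`, `node`, `score`, `matched`, `missing`,
#'   `extraPrivate` (keys), and `ties` (all co-optimal haplogroup names).
#' @export
assignHaplogroup <- function(haplotype, phylo, genome = NULL,
                             missingWeight = 1) {
  keys <- .haplotype_keys(haplotype, genome)
  cand <- which(!is.na(phylo@haplogroup))
  if (!length(cand))
    stop("phylogeny carries no haplogroup labels: cannot assign")
  score <- numeric(length(cand)); matched <- integer(length(cand))
  missing <- integer(length(cand)); depth <- integer(length(cand))
  for (j in seq_along(cand)) {
    exp <- .mp_expected(phylo, cand[j])
    matched[j] <- length(intersect(exp, keys))
    missing[j] <- length(setdiff(exp, keys))
    score[j] <- matched[j] - missingWeight * missing[j]
    depth[j] <- .mp_depth(phylo, cand[j])
  }
  best <- which(score == max(score))
  ties <- best[depth[best] == min(depth[best])]
  pick <- ties[1L]
  list(haplogroup = phylo@haplogroup[cand[pick]],
       node = phylo@label[cand[pick]],
       score = score[pick], matched = matched[pick], missing = missing[pick],
       extraPrivate = setdiff(keys, .mp_expected(phylo, cand[pick])),
       ties = phylo@haplogroup[cand[ties]])
}

.haplotype_keys <- function(haplotype, genome = NULL) {
  if (is(haplotype, "HaplotypeProfile"))
    vapply(haplotype@variants, variantKey, character(1))
  else if (is.character(haplotype))
    vapply(parseVariantLabels(haplotype, genome), variantKey, character(1))
  else if (is.list(haplotype))
    vapply(haplotype, variantKey, character(1))
  else stop("unsupported haplotype representation")
}

#' Count independent mutational origins of a variant
#'
#' Given presence/absence of a variant at every leaf, counts the minimal
#' number of separate acquisitions on the tree.  The default
#' (`mode = "irreversible"`) is gains-only (Camin-Sokal) parsimony: no
#' reversions are allowed, so the count is the number of maximal
#' carrier-pure subtrees.  `mode = "reversible"` runs minimum-change (Fitch)
#' parsimony and reports the number of gains in the gain-maximal
#' most-parsimonious reconstruction.
#'
#' @param phylo a [MitoPhylo-class].
#' @param carrierStates named logical (or 0/1) vector over all leaf labels.
#' @param mode `"irreversible"` (default) or `"reversible"`.
#' @param variant label recorded in the result.
#' @return an [OriginCount-class].
#' @export
countIndependentOrigins <- function(phylo, carrierStates,
                                    mode = c("irreversible", "reversible"),
                                    variant = NA_character_) {
  mode <- match.arg(mode)
  leaves <- .mp_leaves(phylo)
  labs <- phylo@label[leaves]
  if (is.numeric(carrierStates)) carrierStates <- carrierStates > 0
  missing <- setdiff(labs, names(carrierStates))
  if (length(missing))
    stop("missing carrier state for leaf/leaves: ",
         paste(missing, collapse = ", "))
  st <- carrierStates[labs]
  if (anyNA(st)) stop("carrier states must be TRUE/FALSE for every leaf")
  if (!any(st))
    return(new("OriginCount", variant = variant, nOrigins = 0L,
               originBranches = character(0), mode = mode))

  n <- length(phylo@label)
  isLeaf <- seq_len(n) %in% leaves
  state <- rep(NA, n); state[leaves] <- st

  if (mode == "irreversible") {
    # pure[v]: all leaves under v are carriers
    pure <- logical(n)
    ord <- order(vapply(seq_len(n), function(i) .mp_depth(phylo, i),
                        integer(1)), decreasing = TRUE)
    for (v in ord) {
      kids <- .mp_children(phylo, v)
      pure[v] <- if (!length(kids)) isTRUE(state[v]) else all(pure[kids])
    }
    origins <- which(vapply(seq_len(n), function(v) {
      pure[v] && (is.na(phylo@parent[v]) || !pure[phylo@parent[v]])
    }, logical(1)))
    # report each gain on the branch above the MRCA of its carrier leaves
    # (on a chain of single-descendant nodes the gain is equally
    # parsimonious anywhere; the tipward-most placement is reported)
    branches <- vapply(origins, function(v) {
      lv <- leaves[vapply(leaves, function(x) v %in% .mp_path(phylo, x),
                          logical(1)) & st]
      common <- Reduce(intersect, lapply(lv, function(x) .mp_path(phylo, x)))
      phylo@label[common[length(common)]]
    }, character(1))
    return(new("OriginCount", variant = variant,
               nOrigins = length(branches), originBranches = branches,
               mode = mode))
  }

  # reversible: Sankoff with unit costs; among minimum-change reconstructions
  # prefer the one with the most gains, tracked lexicographically
  INF <- 1e9
  cost <- matrix(INF, n, 2)    # columns: state 0, state 1
  gain <- matrix(-INF, n, 2)   # max gains achievable at that cost
  choice <- vector("list", n)  # per node, per state: chosen child states
  ord <- order(vapply(seq_len(n), function(i) .mp_depth(phylo, i),
                      integer(1)), decreasing = TRUE)
  for (v in ord) {
    kids <- .mp_children(phylo, v)
    if (!length(kids)) {
      s <- as.integer(state[v])
      cost[v, s + 1L] <- 0; gain[v, s + 1L] <- 0
      next
    }
    choice[[v]] <- list(`0` = integer(0), `1` = integer(0))
    for (s in 0:1) {
      tot <- 0; g <- 0; pick <- integer(length(kids))
      for (ki in seq_along(kids)) {
        k <- kids[ki]
        bestC <- INF; bestG <- -INF; bestT <- NA_integer_
        for (t in 0:1) {
          c2 <- cost[k, t + 1L] + (s != t)
          g2 <- gain[k, t + 1L] + (s == 0 && t == 1)
          if (c2 < bestC || (c2 == bestC && g2 > bestG)) {
            bestC <- c2; bestG <- g2; bestT <- t
          }
        }
        tot <- tot + bestC; g <- g + bestG; pick[ki] <- bestT
      }
      cost[v, s + 1L] <- tot; gain[v, s + 1L] <- g
      choice[[v]][[as.character(s)]] <- pick
    }
  }
  root <- .mp_root(phylo)
  # a root already in the carrier state contributes one origin itself
  rootState <- if (cost[root, 1] < cost[root, 2]) 0L
    else if (cost[root, 2] < cost[root, 1]) 1L
    else if (gain[root, 2] + 1 > gain[root, 1]) 1L else 0L
  # reconstruct gains
  branches <- character(0)
  walk <- function(v, s) {
    kids <- .mp_children(phylo, v)
    if (!length(kids)) return(invisible())
    pick <- choice[[v]][[as.character(s)]]
    for (ki in seq_along(kids)) {
      k <- kids[ki]; t <- pick[ki]
      if (s == 0L && t == 1L) branches <<- c(branches, phylo@label[k])
      walk(k, t)
    }
  }
  walk(root, rootState)
  if (rootState == 1L)  # the variant predates the tree root
    branches <- c(phylo@label[root], branches)
  new("OriginCount", variant = variant, nOrigins = length(branches),
      originBranches = branches, mode = mode)
}

#' Flag mutations recurring on several branches
#'
#' Exact multiset accounting over all branch mutation lists; labels differing
#' only in heteroplasmy (or effect/locus hints) collapse onto one key.
#'
#' @param phylo a [MitoPhylo-class].
#' @return data.frame with `key`, `count` and `branches` for every mutation
#'   appearing on two or more branches.
#' @export
flagRecurrentMutations <- function(phylo) {
  keys <- unlist(phylo@mutationKeys, use.names = FALSE)
  at <- rep(phylo@label, lengths(phylo@mutationKeys))
  if (!length(keys))
    return(data.frame(key = character(0), count = integer(0),
                      branches = character(0)))
  tab <- table(keys)
  rec <- names(tab)[tab >= 2L]
  data.frame(
    key = rec,
    count = as.integer(tab[rec]),
    branches = vapply(rec, function(k)
      paste(at[keys == k], collapse = ","), character(1)),
    row.names = NULL)
}

#' Classify a variant as ancient or recent
#'
#' A variant carried by a haplotype is *ancient* when it is part of the
#' haplogroup-defining motif (a branch mutation on the root-to-assigned-node
#' path) and *recent* (private) otherwise.
#'
#' @param variant a [MitoVariant-class] or label.
#' @param haplotype the carrier haplotype (see [assignHaplogroup()]).
#' @param phylo a [MitoPhylo-class].
#' @param genome optional genome for label resolution.
#' @return `"ancient"` or `"recent"`.
#' @export
classifyVariantAge <- function(variant, haplotype, phylo, genome = NULL) {
  if (is.character(variant)) variant <- parseVariantLabel(variant, genome)
  asg <- assignHaplogroup(haplotype, phylo, genome)
  node <- match(asg$node, phylo@label)
  if (variantKey(variant) %in% .mp_expected(phylo, node)) "ancient" else "recent"
}

#' Haplogroup enrichment of a cohort against a population frequency
#'
#' @param assignments character vector of per-sample haplogroup names.
#' @param targetClades clade names; a sample counts when its haplogroup is
#'   the clade or any subclade.  Membership is decided under `phylo` when the
#'   clade is a named node there (all haplogroup names in its subtree);
#'   otherwise by name-prefix.
#' @param populationFrequency the clade-set frequency in the general
#'   population, in (0, 1].
#' @param phylo optional [MitoPhylo-class] for tree-based membership.
#' @return list with `cohortFraction`, `foldEnrichment`, `nCarriers`, `n`.
#' @examples
#' haplogroupEnrichment(c("J1c2", "H", "J2b1", "H"), c("J1c", "J2b"), 0.062)
#' @export
haplogroupEnrichment <- function(assignments, targetClades,
                                 populationFrequency, phylo = NULL) {
  if (!length(assignments)) stop("empty cohort")
  if (populationFrequency <= 0 || populationFrequency > 1)
    stop("population frequency must be in (0, 1]")
  member <- rep(FALSE, length(assignments))
  for (clade in targetClades) {
    names_in <- clade
    if (!is.null(phylo) && clade %in% phylo@haplogroup) {
      node <- which(phylo@haplogroup == clade)
      sub <- node
      repeat {
        more <- which(phylo@parent %in% sub & !seq_along(phylo@parent) %in% sub)
        if (!length(more)) break
        sub <- c(sub, more)
      }
      names_in <- phylo@haplogroup[sub]
      names_in <- names_in[!is.na(names_in)]
    }
    member <- member | assignments %in% names_in |
      startsWith(assignments, clade)
  }
  frac <- mean(member)
  list(cohortFraction = frac,
       foldEnrichment = frac / populationFrequency,
       nCarriers = sum(member), n = length(assignments))
}
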