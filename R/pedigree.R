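#' Simulate an extended outbred pedigree from a single founder couple
#'
#' Generation 0 holds one founder couple. Each couple draws a
#' Poisson(`mean_offspring`) number of children; every child who reproduces
#' is paired with a new unrelated founder spouse drawn into the pedigree at
#' the child's generation. There is no inbreeding: the only path between any
#' two blood descendants runs through the founder couple, which keeps
#' IBD-sharing logic (and the all-carriers imputation rule) clean.
#'
#' @param n_generations pedigree depth, >= 2 (generation indices 0..n-1).
#' @param mean_offspring Poisson mean number of children per couple.
#' @param seed integer seed.
#' @param p_reproduce probability a child forms a couple (before the final
#'   generation); limits uncontrolled growth.
#' @return data.table with columns `id`, `father`, `mother` (NA for
#'   founders), `generation`, `founder` (logical).
#' @export
simulate_pedigree <- function(n_generations, mean_offspring, seed,
                              p_reproduce = 0.8) {
  if (n_generations < 2L) stop("n_generations must be >= 2")
  if (mean_offspring <= 0) stop("mean_offspring must be > 0")
  set.seed(as.integer(seed))
  nid <- 0L
  new_id <- function() { nid <<- nid + 1L; sprintf("I%04d", nid) }

  rows <- list()
  add <- function(id, fa, mo, gen, fo)
    rows[[length(rows) + 1L]] <<- data.table(
      id = id, father = fa, mother = mo, generation = gen, founder = fo)

  f0 <- new_id(); m0 <- new_id()
  add(f0, NA_character_, NA_character_, 0L, TRUE)
  add(m0, NA_character_, NA_character_, 0L, TRUE)
  couples <- list(c(f0, m0))

  for (g in seq_len(n_generations - 1L)) {
    nxt <- list()
    for (cp in couples) {
      k <- stats::rpois(1L, mean_offspring)
      for (j in seq_len(k)) {
        child <- new_id()
        add(child, cp[1], cp[2], g, FALSE)
        reproduces <- g < (n_generations - 1L) &&
          stats::runif(1) < p_reproduce
        if (reproduces) {
          spouse <- new_id()
          add(spouse, NA_character_, NA_character_, g, TRUE)
          nxt[[length(nxt) + 1L]] <- c(child, spouse)
        }
      }
    }
    had_children <- any(vapply(rows, function(r) r$generation[1] == g &&
                                 !r$founder[1], TRUE))
    if (!had_children || (length(nxt) == 0L && g < (n_generations - 1L)))
      stop("pedigree went extinct at generation ", g,
           " before requested depth ", n_generations)
    couples <- nxt
  }
  ped <- rbindlist(rows)
  setkey(ped, id)
  ped[]
}

#' Simulate a pedigree conditioned on reaching the requested depth
#'
#' A single-couple branching process goes extinct before depth with
#' appreciable probability; real study pedigrees of this kind are
#' ascertained precisely because they are large. This wrapper retries
#' [simulate_pedigree()] with derived sub-seeds until the requested depth is
#' reached, emulating that ascertainment.
#'
#' @inheritParams simulate_pedigree
#' @param max_tries attempts before giving up.
#' @export
simulate_pedigree_surviving <- function(n_generations, mean_offspring, seed,
                                        p_reproduce = 0.8, max_tries = 200L) {
  for (k in seq_len(max_tries)) {
    sub <- (as.integer(seed) + 7907L * (k - 1L)) %% .Machine$integer.max
    ped <- tryCatch(
      simulate_pedigree(n_generations, mean_offspring, sub, p_reproduce),
      error = function(e) NULL)
    if (!is.null(ped)) return(ped)
  }
  stop("no surviving pedigree in ", max_tries, " attempts")
}

#' Validate pedigree structural invariants
#'
#' Checks acyclicity by generation ordering: founders have no parents,
#' non-founders have exactly two parents from strictly earlier generations.
#' @param ped pedigree data.table from [simulate_pedigree()].
#' @return TRUE invisibly; stops on violation.
#' @export
validate_pedigree <- function(ped) {
  ped <- as.data.table(ped)
  fo <- ped[founder == TRUE]
  if (!all(is.na(fo$father)) || !all(is.na(fo$mother)))
    stop("founders must have no parents")
  nf <- ped[founder == FALSE]
  if (nrow(nf)) {
    if (anyNA(nf$father) || anyNA(nf$mother))
      stop("non-founders must have two parents")
    gen <- stats::setNames(ped$generation, ped$id)
    if (any(gen[nf$father] >= nf$generation) ||
        any(gen[nf$mother] >= nf$generation))
      stop("parents must come from earlier generations")
  }
  invisible(TRUE)
}

#' Construct a chain-of-descent pedigree for a relative pair
#'
#' Builds a pedigree in which two target individuals are separated by
#' exactly `m` meioses through a shared ancestral couple (two branches of
#' depth `a` and `m - a`). Used to study the meioses estimator on pairs of
#' known relationship: `m = 2` gives full siblings, `m = 4` first cousins.
#'
#' @param m meioses separation, >= 2.
#' @param a depth of the first branch (default balanced split).
#' @return list(ped = pedigree data.table, pair = character ids of the two
#'   related individuals).
#' @export
relative_pair_pedigree <- function(m, a = m %/% 2L) {
  if (m < 2L || a < 1L || (m - a) < 1L) stop("need m >= 2 with valid split")
  b <- m - a
  rows <- list()
  add <- function(id, fa, mo, gen, fo)
    rows[[length(rows) + 1L]] <<- data.table(
      id = id, father = fa, mother = mo, generation = gen, founder = fo)
  add("A0", NA_character_, NA_character_, 0L, TRUE)
  add("B0", NA_character_, NA_character_, 0L, TRUE)
  branch <- function(tag, depth) {
    prev <- c("A0", "B0")
    for (g in seq_len(depth)) {
      child <- sprintf("%s%d", tag, g)
      add(child, prev[1], prev[2], g, FALSE)
      if (g < depth) {
        sp <- sprintf("%sS%d", tag, g)
        add(sp, NA_character_, NA_character_, g, TRUE)
        prev <- c(child, sp)
      }
    }
    sprintf("%s%d", tag, depth)
  }
  left <- branch("L", a)
  right <- branch("R", b)
  ped <- rbindlist(rows)
  setkey(ped, id)
  list(ped = ped[], pair = c(left, right))
}
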