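#' Read an FCIDUMP integral file
#'
#' Parses the standard FCIDUMP text format: a namelist-style header
#' (`&FCI NORB=..., NELEC=..., MS2=..., ORBSYM=..., ISYM=..., &END` or
#' `/`) followed by lines `value i j k l`.  Lines with `k = l = 0` carry
#' one-body integrals `h1[i,j]`, the all-zero-index line carries the core
#' energy, and all remaining lines are chemist-notation two-electron
#' integrals `(ij|kl)` with 1-based indices.  Each stored unique integral
#' is expanded to its full 8-fold symmetric orbit.  `ORBSYM`/`ISYM` are
#' read but ignored (all orbitals treated as totally symmetric).  Complex
#' integrals are rejected.
#'
#' @param path Path to an FCIDUMP file.
#' @return An `asham` object.  The electron counts are split from
#'   `NELEC`/`MS2` as `n_alpha = (NELEC + MS2)/2`.
#' @export
read_fcidump <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("malformed FCIDUMP: empty file")

  # --- header: everything from &FCI up to &END or a bare "/"
  hdr_end <- NA_integer_
  for (i in seq_along(lines)) {
    if (grepl("&END", lines[i], ignore.case = TRUE) ||
        grepl("(^|[[:space:]])/([[:space:]]|$)", lines[i]) ||
        grepl("/\\s*$", lines[i])) { hdr_end <- i; break }
  }
  if (is.na(hdr_end)) stop("malformed FCIDUMP: header terminator not found")
  header <- paste(lines[seq_len(hdr_end)], collapse = " ")
  if (!grepl("&FCI", header, ignore.case = TRUE))
    stop("malformed FCIDUMP: missing &FCI header")

  get_field <- function(name) {
    m <- regmatches(header,
                    regexpr(paste0(name, "\\s*=\\s*-?[0-9]+"), header,
                            ignore.case = TRUE))
    if (!length(m)) return(NA_integer_)
    as.integer(sub(".*=\\s*", "", m))
  }
  norb <- get_field("NORB")
  nelec <- get_field("NELEC")
  ms2 <- get_field("MS2")
  if (is.na(norb) || is.na(nelec) || is.na(ms2))
    stop("malformed FCIDUMP: header must declare NORB, NELEC, MS2")
  if (norb < 1) stop("malformed FCIDUMP: NORB must be positive")

  n_alpha <- (nelec + ms2) %/% 2L
  n_beta <- nelec - n_alpha

  h1 <- matrix(0, norb, norb)
  eri <- array(0, rep(norb, 4))
  e_core <- 0
  seen1 <- matrix(FALSE, norb, norb)
  seen2 <- array(FALSE, rep(norb, 4))

  body <- lines[-seq_len(hdr_end)]
  body <- body[nzchar(trimws(body))]
  for (ln in body) {
    if (grepl("[(]", ln))
      stop("complex-valued FCIDUMP integrals are not supported")
    tok <- strsplit(trimws(ln), "[[:space:],]+")[[1]]
    if (length(tok) != 5L)
      stop("malformed FCIDUMP line: ", ln)
    val <- suppressWarnings(as.numeric(tok[1]))
    idx <- suppressWarnings(as.integer(tok[2:5]))
    if (is.na(val) || anyNA(idx))
      stop("malformed FCIDUMP line: ", ln)
    if (any(idx < 0) || any(idx > norb))
      stop("FCIDUMP index out of range in line: ", ln)
    i <- idx[1]; j <- idx[2]; k <- idx[3]; l <- idx[4]
    if (all(idx == 0L)) {
      e_core <- val
    } else if (k == 0L && l == 0L) {
      if (i == 0L || j == 0L)
        stop("FCIDUMP index out of range in line: ", ln)
      if ((seen1[i, j] && abs(h1[i, j] - val) > 1e-12))
        stop("contradictory duplicate one-body integral at (", i, ",", j, ")")
      h1[i, j] <- val; h1[j, i] <- val
      seen1[i, j] <- TRUE; seen1[j, i] <- TRUE
    } else {
      if (any(idx == 0L))
        stop("FCIDUMP index out of range in line: ", ln)
      orb <- eri_orbit(i, j, k, l)
      dup <- seen2[orb]
      if (any(dup) && any(abs(eri[orb] - val) > 1e-12))
        stop("contradictory duplicate two-electron integral at (",
             i, " ", j, "|", k, " ", l, ")")
      eri[orb] <- val
      seen2[orb] <- TRUE
    }
  }
  active_space_hamiltonian(norb, n_alpha, n_beta, e_core, h1, eri,
                           multiplicity = ms2 + 1L, validate = FALSE)
}

# linear indices (into an N^4 array) of the 8-fold symmetry orbit of (ij|kl)
eri_orbit <- function(i, j, k, l) {
  perms <- rbind(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k), c(j, i, l, k),
                 c(k, l, i, j), c(l, k, i, j), c(k, l, j, i), c(l, k, j, i))
  unique(perms)
}

#' Write an FCIDUMP integral file
#'
#' Emits only symmetry-unique integrals with magnitude above
#' `threshold`, in deterministic descending index order, so two writes of
#' the same Hamiltonian are byte-identical and a write/read roundtrip is
#' the identity (up to the threshold).  The core energy is always written
#' on the final all-zero-index line.
#'
#' @param h An `asham` object.
#' @param path Output path.
#' @param threshold Magnitude below which integrals are dropped
#'   (default 1e-12).
#' @return `path`, invisibly.
#' @export
write_fcidump <- function(h, path, threshold = 1e-12) {
  stopifnot(inherits(h, "asham"))
  n <- h$n_orb
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  ms2 <- h$n_alpha - h$n_beta
  writeLines(c(sprintf(" &FCI NORB=%d,NELEC=%d,MS2=%d,", n,
                       h$n_alpha + h$n_beta, ms2),
               sprintf("  ORBSYM=%s", paste(rep("1,", n), collapse = "")),
               "  ISYM=1,", " &END"), con)
  fmt <- function(v, i, j, k, l) sprintf("%23.16E %4d %4d %4d %4d", v, i, j, k, l)
  out <- character(0)
  # two-electron: unique canonical quadruples ij >= kl blocks, descending
  for (i in n:1) for (j in i:1) for (k in i:1) {
    lmax <- if (k == i) j else k
    for (l in lmax:1) {
      v <- h$eri[i, j, k, l]
      if (abs(v) > threshold) out <- c(out, fmt(v, i, j, k, l))
    }
  }
  for (i in n:1) for (j in i:1) {
    v <- h$h1[i, j]
    if (abs(v) > threshold) out <- c(out, fmt(v, i, j, 0L, 0L))
  }
  out <- c(out, fmt(h$e_core, 0L, 0L, 0L, 0L))
  writeLines(out, con)
  invisible(path)
}
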