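# Linear and mixed-integer programming through the GLPK command-line
# solver (glpsol). Problems are written in CPLEX-LP format to a
# temporary file and the machine-readable solution (-w) is parsed back.
# Deterministic: identical input files give identical solver paths.

.glpsolPath <- function() {
  p <- Sys.which("glpsol")
  if (!nzchar(p))
    stop("the GLPK solver 'glpsol' was not found on the PATH")
  p
}

.lpNum <- function(x) sprintf("%.17g", x)

# obj: numeric n; mat: constraint matrix (dense or sparse) m x n;
# dir: character m in "=", "<=", ">="; rhs: numeric m;
# lb/ub: numeric n (may be +-Inf); sense: "max"/"min";
# intIdx: indices of binary variables.
.solveLP <- function(obj, mat, dir, rhs, lb, ub, sense = "max",
                     intIdx = integer(0)) {
  n <- length(obj)
  m <- length(rhs)
  mat <- as(as(Matrix::Matrix(mat, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  vnames <- paste0("x", seq_len(n))
  lines <- character()
  lines <- c(lines, if (sense == "max") "Maximize" else "Minimize")
  # list every variable (zero coefficients included) so glpsol's column
  # order matches x1..xn and the -w solution indices map back directly
  objterms <- paste(sprintf("%+.17g %s", obj, vnames), collapse = " ")
  lines <- c(lines, paste0(" obj: ", objterms))
  lines <- c(lines, "Subject To")
  ti <- mat@i + 1L; tj <- mat@j + 1L; tx <- mat@x
  ord <- order(ti, tj)
  ti <- ti[ord]; tj <- tj[ord]; tx <- tx[ord]
  terms_by_row <- split(sprintf("%+.17g %s", tx, vnames[tj]), ti)
  op <- c("=" = "=", "<=" = "<=", ">=" = ">=")[dir]
  for (i in seq_len(m)) {
    tt <- terms_by_row[[as.character(i)]]
    lhs <- if (is.null(tt)) paste0("0 ", vnames[1L]) else paste(tt, collapse = " ")
    lines <- c(lines, sprintf(" c%d: %s %s %s", i, lhs, op[i], .lpNum(rhs[i])))
  }
  lines <- c(lines, "Bounds")
  for (j in seq_len(n)) {
    if (is.infinite(lb[j]) && is.infinite(ub[j])) {
      lines <- c(lines, sprintf(" %s free", vnames[j]))
    } else if (is.infinite(lb[j])) {
      lines <- c(lines, sprintf(" -inf <= %s <= %s", vnames[j], .lpNum(ub[j])))
    } else if (is.infinite(ub[j])) {
      lines <- c(lines, sprintf(" %s >= %s", vnames[j], .lpNum(lb[j])))
    } else {
      lines <- c(lines, sprintf(" %s <= %s <= %s", .lpNum(lb[j]), vnames[j],
                                .lpNum(ub[j])))
    }
  }
  if (length(intIdx)) {
    lines <- c(lines, "Binary", paste0(" ", vnames[intIdx]))
  }
  lines <- c(lines, "End")

  lpf <- tempfile(fileext = ".lp")
  solf <- tempfile(fileext = ".sol")
  on.exit(unlink(c(lpf, solf)), add = TRUE)
  writeLines(lines, lpf)
  out <- suppressWarnings(system2(.glpsolPath(), c("--lp", shQuote(lpf), "-w",
                                                   shQuote(solf)),
                                  stdout = TRUE, stderr = TRUE))
  if (!file.exists(solf))
    stop("glpsol failed: ", paste(utils::tail(out, 3), collapse = " / "))
  sol <- readLines(solf)
  status_line <- grep("^c Status:", sol, value = TRUE)
  status <- trimws(sub("^c Status:", "", status_line[1]))
  if (!status %in% c("OPTIMAL", "INTEGER OPTIMAL")) {
    if (any(grepl("NO PRIMAL FEASIBLE", out)) ||
        any(grepl("NO.*INTEGER FEASIBLE", out)) ||
        any(grepl("LP RELAXATION.*NO", out)))
      stop("LP infeasible")
    if (any(grepl("NO DUAL FEASIBLE", out)) || any(grepl("UNBOUNDED", out)))
      stop("LP unbounded")
    stop("LP solve failed with status: ", status)
  }
  jlines <- grep("^j ", sol, value = TRUE)
  x <- numeric(n)
  mip <- length(intIdx) > 0L
  for (ln in jlines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    idx <- as.integer(f[2])
    x[idx] <- if (mip) as.numeric(f[3]) else as.numeric(f[4])
  }
  objval <- sum(obj * x)
  list(x = x, objval = objval, status = status)
}
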