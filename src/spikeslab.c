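/* Incremental-Cholesky model state and Metropolis-Hastings indicator
 * kernels.  This is the performance-critical engine behind runChain();
 * the R sources contain reference implementations of the same mathematics
 * used as oracles in the test suite, and the delayed-rejection audit
 * recomputes every second-stage acceptance ratio independently in R.
 *
 * State layout: with q included variants, A = X'X + diag(1/tau^2) = R'R
 * (R upper triangular, column-major), w = R^{-T} X'y and
 * S = y'y - w'w.  Additions are rank-one Cholesky updates, removals are
 * Givens-based column deletions, and a full refactorization every
 * refactorInterval modifications resets floating-point drift.
 */

#define USE_FC_LEN_T
#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif

#define OP_ADD 1
#define OP_REMOVE (-1)

typedef struct {
    int n, m;
    double *X;          /* n x m column-major (copy) */
    double *y;          /* n */
    double *Xty;        /* m */
    double *colSq;      /* m */
    double yty;
    double mlConst, mlCoef, nuSigma, s2Sigma;
    double *priorTab;   /* m + 1: log prior of a configuration of size q */
    double *tau2full;   /* m: slab variance used when a variant is added */
    int *orderPos;      /* m: 0-based genomic position of each variant */
    int *orderVar;      /* m: variant at each 0-based position */
    /* factor */
    int cap, q;
    double *R;          /* cap x cap upper triangular, column-major */
    double *w;          /* cap */
    double *tau2incl;   /* cap, aligned with incl */
    int *incl;          /* cap, insertion order */
    int *inModel;       /* m, 0/1 */
    double sumLogTau2, sumLogDiagR;
    int nMods, refactorInterval;
    double logpost, logml;
    double *scrA;       /* cap x cap scratch for refactorization */
    double *scrV;       /* cap scratch */
} MState;

/* ---------------- state management ---------------- */

static void state_free(SEXP ptr)
{
    MState *st = (MState *) R_ExternalPtrAddr(ptr);
    if (!st) return;
    free(st->X); free(st->y); free(st->Xty); free(st->colSq);
    free(st->priorTab); free(st->tau2full);
    free(st->orderPos); free(st->orderVar);
    free(st->R); free(st->w); free(st->tau2incl); free(st->incl);
    free(st->inModel); free(st->scrA); free(st->scrV);
    free(st);
    R_ClearExternalPtr(ptr);
}

static MState *state_get(SEXP ptr)
{
    MState *st = (MState *) R_ExternalPtrAddr(ptr);
    if (!st) error("invalid (finalized) model state pointer");
    return st;
}

static void state_recache(MState *st)
{
    double S = st->yty;
    for (int i = 0; i < st->q; i++) S -= st->w[i] * st->w[i];
    st->logml = -0.5 * st->sumLogTau2 - st->sumLogDiagR + st->mlConst
        - st->mlCoef * log1p(S / (st->nuSigma * st->s2Sigma));
    st->logpost = st->logml + st->priorTab[st->q];
}

static void state_grow(MState *st)
{
    int cap = st->cap;
    int newCap = 2 * cap;
    if (newCap > st->n) newCap = st->n;
    if (newCap <= cap) error("internal error: cannot grow factor storage");
    double *R2 = calloc((size_t) newCap * newCap, sizeof(double));
    double *A2 = calloc((size_t) newCap * newCap, sizeof(double));
    double *w2 = calloc(newCap, sizeof(double));
    double *t2 = calloc(newCap, sizeof(double));
    double *v2 = calloc(newCap, sizeof(double));
    int *i2 = calloc(newCap, sizeof(int));
    if (!R2 || !A2 || !w2 || !t2 || !v2 || !i2) error("out of memory");
    for (int j = 0; j < cap; j++)
        memcpy(R2 + (size_t) j * newCap, st->R + (size_t) j * cap,
               cap * sizeof(double));
    memcpy(w2, st->w, cap * sizeof(double));
    memcpy(t2, st->tau2incl, cap * sizeof(double));
    memcpy(i2, st->incl, cap * sizeof(int));
    free(st->R); free(st->scrA); free(st->w); free(st->tau2incl);
    free(st->scrV); free(st->incl);
    st->R = R2; st->scrA = A2; st->w = w2; st->tau2incl = t2;
    st->scrV = v2; st->incl = i2;
    st->cap = newCap;
}

static void state_refactor(MState *st)
{
    int q = st->q, n = st->n, cap = st->cap;
    st->nMods = 0;
    if (q == 0) { st->sumLogTau2 = 0.0; st->sumLogDiagR = 0.0; return; }
    double *A = st->scrA;
    for (int cj = 0; cj < q; cj++) {
        const double *xj = st->X + (size_t) st->incl[cj] * n;
        for (int ci = 0; ci <= cj; ci++) {
            const double *xi = st->X + (size_t) st->incl[ci] * n;
            double s = 0.0;
            for (int t = 0; t < n; t++) s += xi[t] * xj[t];
            A[ci + (size_t) cj * q] = s;
        }
        A[cj + (size_t) cj * q] += 1.0 / st->tau2incl[cj];
    }
    int info = 0;
    F77_CALL(dpotrf)("U", &q, A, &q, &info FCONE);
    if (info != 0) error("Cholesky refactorization failed (info = %d)", info);
    for (int cj = 0; cj < q; cj++) {
        for (int ci = 0; ci <= cj; ci++)
            st->R[ci + (size_t) cj * cap] = A[ci + (size_t) cj * q];
        for (int ci = cj + 1; ci < q; ci++)
            st->R[ci + (size_t) cj * cap] = 0.0;
    }
    /* w = R^{-T} Xty_incl (forward substitution) */
    double slt = 0.0, sld = 0.0;
    for (int t = 0; t < q; t++) {
        double s = st->Xty[st->incl[t]];
        for (int i = 0; i < t; i++) s -= st->R[i + (size_t) t * cap] * st->w[i];
        st->w[t] = s / st->R[t + (size_t) t * cap];
        slt += log(st->tau2incl[t]);
        sld += log(st->R[t + (size_t) t * cap]);
    }
    st->sumLogTau2 = slt;
    st->sumLogDiagR = sld;
}

/* Add variant j (0-based) with slab variance tau2j.  Returns 1 on success,
 * 0 when saturated or the pivot is numerically non-positive. */
static int state_add(MState *st, int j, double tau2j)
{
    int q = st->q, n = st->n;
    if (st->inModel[j]) error("internal error: variant already included");
    if (tau2j <= 0) error("invalid prior: tau2 must be positive");
    if (q + 1 > st->n - 2) return 0;
    if (q + 1 > st->cap) state_grow(st);
    int cap = st->cap;
    double *r12 = st->scrV;
    double d = st->colSq[j] + 1.0 / tau2j;
    const double *xj = st->X + (size_t) j * n;
    for (int t = 0; t < q; t++) {
        const double *xc = st->X + (size_t) st->incl[t] * n;
        double s = 0.0;
        for (int i = 0; i < n; i++) s += xc[i] * xj[i];
        r12[t] = s;
    }
    for (int t = 0; t < q; t++) {
        double s = r12[t];
        for (int i = 0; i < t; i++) s -= st->R[i + (size_t) t * cap] * r12[i];
        r12[t] = s / st->R[t + (size_t) t * cap];
        d -= r12[t] * r12[t];
    }
    if (d <= 1e-12 * (st->colSq[j] + 1.0 / tau2j)) {
        warning("refusing to add variant %d: non-positive pivot", j + 1);
        return 0;
    }
    double r22 = sqrt(d);
    double wnum = st->Xty[j];
    for (int t = 0; t < q; t++) {
        st->R[t + (size_t) q * cap] = r12[t];
        wnum -= r12[t] * st->w[t];
    }
    st->R[q + (size_t) q * cap] = r22;
    st->w[q] = wnum / r22;
    st->tau2incl[q] = tau2j;
    st->incl[q] = j;
    st->inModel[j] = 1;
    st->q = q + 1;
    st->sumLogTau2 += log(tau2j);
    st->sumLogDiagR += log(r22);
    st->nMods++;
    if (st->nMods >= st->refactorInterval) state_refactor(st);
    state_recache(st);
    return 1;
}

/* Remove included variant j (0-based); Givens-based column deletion. */
static void state_remove(MState *st, int j)
{
    int q = st->q, cap = st->cap, p = -1;
    for (int t = 0; t < q; t++) if (st->incl[t] == j) { p = t; break; }
    if (p < 0) error("internal error: variant not included");
    st->sumLogTau2 -= log(st->tau2incl[p]);
    if (p < q - 1) {
        for (int c = p; c < q - 1; c++) {
            memcpy(st->R + (size_t) c * cap, st->R + (size_t) (c + 1) * cap,
                   q * sizeof(double));
            st->tau2incl[c] = st->tau2incl[c + 1];
            st->incl[c] = st->incl[c + 1];
        }
        for (int i = p; i < q - 1; i++) {
            double a = st->R[i + (size_t) i * cap];
            double b = st->R[(i + 1) + (size_t) i * cap];
            double r = hypot(a, b);
            if (r > 0) {
                double c0 = a / r, s0 = b / r;
                for (int c = i; c < q - 1; c++) {
                    double ri = st->R[i + (size_t) c * cap];
                    double ri1 = st->R[(i + 1) + (size_t) c * cap];
                    st->R[i + (size_t) c * cap] = c0 * ri + s0 * ri1;
                    st->R[(i + 1) + (size_t) c * cap] = -s0 * ri + c0 * ri1;
                }
                double wi = st->w[i], wi1 = st->w[i + 1];
                st->w[i] = c0 * wi + s0 * wi1;
                st->w[i + 1] = -s0 * wi + c0 * wi1;
            }
        }
    }
    int qn = q - 1;
    for (int i = 0; i < q; i++) st->R[i + (size_t) qn * cap] = 0.0;
    for (int c = 0; c < qn; c++) st->R[qn + (size_t) c * cap] = 0.0;
    st->w[qn] = 0.0;
    st->inModel[j] = 0;
    st->q = qn;
    double sld = 0.0;
    for (int t = 0; t < qn; t++) sld += log(st->R[t + (size_t) t * cap]);
    st->sumLogDiagR = sld;
    st->nMods++;
    if (st->nMods >= st->refactorInterval) state_refactor(st);
    state_recache(st);
}

/* ---------------- move-size distribution ---------------- */

static double trunc_geom_pmf(int k, double p, int kMax)
{
    if (k < 1 || k > kMax) return 0.0;
    double norm = 1.0 - pow(1.0 - p, kMax);
    return p * pow(1.0 - p, k - 1) / norm;
}

static double trunc_geom_log_tail(int k, double p, int kMax)
{
    if (k <= 1) return 0.0;
    if (k > kMax) return R_NegInf;
    return log(pow(1.0 - p, k - 1) - pow(1.0 - p, kMax))
        - log1p(-pow(1.0 - p, kMax));
}

static double size_log_factor(int len, int exhausted, double p, int kMax)
{
    return exhausted ? trunc_geom_log_tail(len, p, kMax)
                     : log(trunc_geom_pmf(len, p, kMax));
}

static int trunc_geom_sample(double p, int kMax)
{
    double u = unif_rand() * (1.0 - pow(1.0 - p, kMax));
    int k = 1 + (int) floor(log1p(-u) / log1p(-p));
    return k < kMax ? k : kMax;
}

/* weighted draw over w[0..n-1]; returns index */
static int sample_prop(const double *w, int n)
{
    double tot = 0.0;
    for (int i = 0; i < n; i++) tot += w[i];
    double u = unif_rand() * tot, c = 0.0;
    for (int i = 0; i < n; i++) {
        c += w[i];
        if (u < c) return i;
    }
    return n - 1;
}

/* ---------------- move records ---------------- */

typedef struct {
    const char *kernel;
    int kProposed, kDrawn, jump, accepted, drUsed;
    double accProb;
    SEXP detail;  /* R_NilValue or protected list (caller unprotects) */
} Record;

static SEXP record_to_sexp(const Record *rec)
{
    const char *names[] = {"kernel", "kProposed", "kDrawn", "jump",
                           "accepted", "accProb", "drUsed", "detail", ""};
    SEXP out = PROTECT(Rf_mkNamed(VECSXP, names));
    SET_VECTOR_ELT(out, 0, Rf_mkString(rec->kernel));
    SET_VECTOR_ELT(out, 1, Rf_ScalarInteger(rec->kProposed));
    SET_VECTOR_ELT(out, 2, Rf_ScalarInteger(rec->kDrawn));
    SET_VECTOR_ELT(out, 3, Rf_ScalarInteger(rec->jump));
    SET_VECTOR_ELT(out, 4, Rf_ScalarLogical(rec->accepted));
    SET_VECTOR_ELT(out, 5, Rf_ScalarReal(rec->accProb));
    SET_VECTOR_ELT(out, 6, Rf_ScalarLogical(rec->drUsed));
    SET_VECTOR_ELT(out, 7, rec->detail);
    UNPROTECT(1);
    return out;
}

/* DR detail for the R-side audit: 1-based variable order, gamma's states
 * on those variables, the drawn candidate code, and the cached weights. */
static SEXP dr_detail(const int *vars, const int *gammaState, int kk,
                      int pick, double logwGamma, double logwPick,
                      const char *law)
{
    const char *names[] = {"vars", "gammaState", "pick", "logwGamma",
                           "logwPick", "law", ""};
    SEXP out = PROTECT(Rf_mkNamed(VECSXP, names));
    SEXP v = PROTECT(Rf_allocVector(INTSXP, kk));
    SEXP g = PROTECT(Rf_allocVector(LGLSXP, kk));
    for (int i = 0; i < kk; i++) {
        INTEGER(v)[i] = vars[i] + 1;
        LOGICAL(g)[i] = gammaState[i];
    }
    SET_VECTOR_ELT(out, 0, v);
    SET_VECTOR_ELT(out, 1, g);
    SET_VECTOR_ELT(out, 2, Rf_ScalarInteger(pick));
    SET_VECTOR_ELT(out, 3, Rf_ScalarReal(logwGamma));
    SET_VECTOR_ELT(out, 4, Rf_ScalarReal(logwPick));
    SET_VECTOR_ELT(out, 5, Rf_mkString(law));
    UNPROTECT(2);   /* v, g; out stays protected until the wrapper returns */
    return out;
}

/* ---------------- weights-law sequence machinery ---------------- */

/* Exact log-probability of replaying ops/vars from the state described by
 * work[] (0/1, length m) with used[] flags; accumulates direction and
 * variant factors, mutates work/used, and reports terminal exhaustion.
 * Returns the steps-only log-probability (no size factor), or -Inf. */
static double seq_steps_logprob(const double *addW, const double *removeW,
                                int m, int *work, int *used,
                                const int *ops, const int *vars, int len,
                                int *exhaustedOut)
{
    double logq = 0.0;
    for (int s = 0; s < len; s++) {
        int j = vars[s];
        if (used[j]) return R_NegInf;
        int doAdd = ops[s] == OP_ADD;
        if (doAdd && work[j]) return R_NegInf;
        if (!doAdd && !work[j]) return R_NegInf;
        int nAdd = 0, nRem = 0;
        double sumAdd = 0.0, sumRem = 0.0;
        for (int t = 0; t < m; t++) {
            if (used[t]) continue;
            if (work[t]) { nRem++; sumRem += removeW[t]; }
            else { nAdd++; sumAdd += addW[t]; }
        }
        if (nAdd > 0 && nRem > 0) logq += M_LN2 * -1.0;
        logq += doAdd ? log(addW[j]) - log(sumAdd)
                      : log(removeW[j]) - log(sumRem);
        used[j] = 1;
        work[j] = doAdd;
    }
    int any = 0;
    for (int t = 0; t < m; t++) if (!used[t]) { any = 1; break; }
    *exhaustedOut = !any;
    return logq;
}

/* Fast O(k) replay for a DR candidate: the state agrees with gamma outside
 * the move's variable set V; mState gives the start state of each V
 * variable in z order (reversed order when reversed != 0).  Uses the
 * precomputed outside-of-V weight sums.  Includes the size factor. */
static double weight_seq_logq(const double *addW, const double *removeW,
                              const int *vars, const int *mState, int kk,
                              int reversed, double outAddSum, double outRemSum,
                              int outAddN, int outRemN,
                              double pGeom, int kMax)
{
    double addSumV = 0.0, remSumV = 0.0;
    int addNV = 0, remNV = 0;
    for (int i = 0; i < kk; i++) {
        if (mState[i]) { remSumV += removeW[vars[i]]; remNV++; }
        else { addSumV += addW[vars[i]]; addNV++; }
    }
    double logq = 0.0;
    for (int t = 0; t < kk; t++) {
        int i = reversed ? kk - 1 - t : t;
        int v = vars[i];
        int doAdd = !mState[i];
        int nAdd = outAddN + addNV, nRem = outRemN + remNV;
        if (nAdd > 0 && nRem > 0) logq -= M_LN2;
        if (doAdd) {
            logq += log(addW[v]) - log(outAddSum + addSumV);
            addSumV -= addW[v]; addNV--;
        } else {
            logq += log(removeW[v]) - log(outRemSum + remSumV);
            remSumV -= removeW[v]; remNV--;
        }
    }
    int exhausted = (outAddN + outRemN) == 0;
    return logq + size_log_factor(kk, exhausted, pGeom, kMax);
}

/* ---------------- neighborhood-law machinery ---------------- */

/* number of eligible (anchor, neighbor) pairs from configuration inModel
 * with used[] flags; if pickIndex >= 0 the pickIndex-th pair's neighbor is
 * written to *pickVar; if countVar >= 0 its multiplicity is written to
 * *cntOut */
static int nbr_pairs(const MState *st, int cutoff, const int *inModel,
                     const int *used, int pickIndex, int *pickVar,
                     int countVar, int *cntOut)
{
    int total = 0, cnt = 0;
    if (pickVar) *pickVar = -1;
    for (int v = 0; v < st->m; v++) {
        if (!inModel[v]) continue;
        int pos = st->orderPos[v];
        int lo = pos - cutoff; if (lo < 0) lo = 0;
        int hi = pos + cutoff; if (hi > st->m - 1) hi = st->m - 1;
        for (int t = lo; t <= hi; t++) {
            int wv = st->orderVar[t];
            if (wv == v || used[wv]) continue;
            if (pickVar && total == pickIndex) *pickVar = wv;
            if (wv == countVar) cnt++;
            total++;
        }
    }
    if (cntOut) *cntOut = cnt;
    return total;
}

/* generic neighborhood-law replay (including size factor); mutates
 * inModel/used copies supplied by the caller */
static double nbr_seq_logprob(const MState *st, int cutoff, double pNbr,
                              int kMax, int *inModel, int *used,
                              const int *ops, const int *vars, int len)
{
    double logq = 0.0;
    for (int s = 0; s < len; s++) {
        int v = vars[s];
        if (used[v]) return R_NegInf;
        int doAdd = ops[s] == OP_ADD;
        if (doAdd == inModel[v]) return R_NegInf;
        int cnt = 0;
        int total = nbr_pairs(st, cutoff, inModel, used, -1, NULL, v, &cnt);
        if (total == 0 || cnt == 0) return R_NegInf;
        logq += log((double) cnt) - log((double) total);
        inModel[v] = doAdd;
        used[v] = 1;
    }
    int more = nbr_pairs(st, cutoff, inModel, used, -1, NULL, -1, NULL) > 0;
    return logq + size_log_factor(len, !more, pNbr, kMax);
}

/* ---------------- delayed rejection second stage ---------------- */

/* Move the live state between candidate codes (bit b of a code flips the
 * inclusion of vars[b] relative to gammaState). */
static void dr_navigate(MState *st, int from, int to, const int *vars)
{
    int diff = from ^ to;
    for (int b = 0; diff != 0; b++, diff >>= 1) {
        if (diff & 1) {
            int v = vars[b];
            if (st->inModel[v]) state_remove(st, v);
            else if (!state_add(st, v, st->tau2full[v]))
                error("internal error: pivot refused while navigating candidates");
        }
    }
}

/* The second stage after a rejected move gamma -> gamma' through the
 * sequence (ops, vars).  Candidate m's deterministic sequence z_m visits
 * the same variables in the same order, operations set by m's own states
 * (an involution; z_m ends at m XOR V); the candidate is drawn
 * proportional to w(m) = post(m) q(z_m|m) (1 - a1(m -> m XOR V)) and
 * always accepted.  law: 0 = adaptive weights, 1 = neighborhood uniform.
 * Assumes the live state currently sits at gamma'. */
static Record dr_second_stage(MState *st, const int *ops, const int *vars,
                              int kk, double aFirst,
                              const double *addW, const double *removeW,
                              double pGeom, int kMax,
                              int cutoff, double pNbr,
                              int law, int wantDetail, const char *kernel)
{
    Record rec = {kernel, kk, 0, 0, 0, 1, aFirst, R_NilValue};
    int m = st->m;
    int *gammaState = (int *) R_alloc(kk, sizeof(int));
    int nAdds = 0;
    for (int i = 0; i < kk; i++) {
        gammaState[i] = ops[i] == OP_REMOVE;  /* included in gamma iff removed */
        if (ops[i] == OP_ADD) nAdds++;
    }
    int qGamma = st->q - nAdds + (kk - nAdds);
    /* the largest candidate includes every V variable */
    int maxSize = qGamma;
    for (int i = 0; i < kk; i++) if (!gammaState[i]) maxSize++;
    if (maxSize > st->n - 2) {
        /* revert to gamma: undo the applied sequence */
        for (int s = kk - 1; s >= 0; s--) {
            int v = vars[s];
            if (ops[s] == OP_ADD) state_remove(st, v);
            else if (!state_add(st, v, st->tau2full[v]))
                error("internal error: pivot refused while reverting");
        }
        return rec;
    }
    /* outside-of-V sums for the weights law (identical for all candidates) */
    double outAddSum = 0.0, outRemSum = 0.0;
    int outAddN = 0, outRemN = 0;
    int *inV = (int *) R_alloc(m, sizeof(int));
    memset(inV, 0, m * sizeof(int));
    for (int i = 0; i < kk; i++) inV[vars[i]] = 1;
    for (int t = 0; t < m; t++) {
        if (inV[t]) continue;
        if (st->inModel[t]) { outRemSum += removeW ? removeW[t] : 1.0; outRemN++; }
        else { outAddSum += addW ? addW[t] : 1.0; outAddN++; }
    }
    /* walk back to gamma */
    for (int s = kk - 1; s >= 0; s--) {
        int v = vars[s];
        if (ops[s] == OP_ADD) state_remove(st, v);
        else if (!state_add(st, v, st->tau2full[v]))
            error("internal error: pivot refused while reverting");
    }
    /* gamma outside V (for the neighborhood-law replays) */
    int *gammaFull = NULL;
    if (law == 1) {
        gammaFull = (int *) R_alloc(m, sizeof(int));
        memcpy(gammaFull, st->inModel, m * sizeof(int));
    }
    int nSub = 1 << kk;
    double *logpostTab = (double *) R_alloc(nSub, sizeof(double));
    logpostTab[0] = st->logpost;
    int curCode = 0, bad = 0;
    for (int t = 1; t < nSub; t++) {
        int b = 0, tt = t;
        while (!(tt & 1)) { tt >>= 1; b++; }
        int v = vars[b];
        int ok = st->inModel[v] ? (state_remove(st, v), 1)
                                : state_add(st, v, st->tau2full[v]);
        if (!ok) { bad = 1; break; }
        curCode ^= 1 << b;
        logpostTab[curCode] = st->logpost;
    }
    if (bad) {  /* numerically refused pivot: walk home, plain rejection */
        dr_navigate(st, curCode, 0, vars);
        return rec;
    }
    /* per-candidate forward/reverse sequence log-probabilities */
    double *lqF = (double *) R_alloc(nSub, sizeof(double));
    double *lqR = (double *) R_alloc(nSub, sizeof(double));
    int *mState = (int *) R_alloc(kk, sizeof(int));
    int *cState = (int *) R_alloc(kk, sizeof(int));
    int *wrkIn = NULL, *wrkUsed = NULL, *wrkOps = NULL, *wrkVars = NULL;
    if (law == 1) {
        wrkIn = (int *) R_alloc(m, sizeof(int));
        wrkUsed = (int *) R_alloc(m, sizeof(int));
        wrkOps = (int *) R_alloc(kk, sizeof(int));
        wrkVars = (int *) R_alloc(kk, sizeof(int));
    }
    for (int code = 0; code < nSub; code++) {
        for (int i = 0; i < kk; i++) {
            mState[i] = gammaState[i] ^ ((code >> i) & 1);
            cState[i] = !mState[i];
        }
        if (law == 0) {
            lqF[code] = weight_seq_logq(addW, removeW, vars, mState, kk, 0,
                                        outAddSum, outRemSum, outAddN, outRemN,
                                        pGeom, kMax);
            lqR[code] = weight_seq_logq(addW, removeW, vars, cState, kk, 1,
                                        outAddSum, outRemSum, outAddN, outRemN,
                                        pGeom, kMax);
        } else {
            /* forward: replay z_m from m */
            memcpy(wrkIn, gammaFull, m * sizeof(int));
            memset(wrkUsed, 0, m * sizeof(int));
            for (int i = 0; i < kk; i++) {
                wrkIn[vars[i]] = mState[i];
                wrkOps[i] = mState[i] ? OP_REMOVE : OP_ADD;
                wrkVars[i] = vars[i];
            }
            lqF[code] = nbr_seq_logprob(st, cutoff, pNbr, kMax, wrkIn, wrkUsed,
                                        wrkOps, wrkVars, kk);
            /* reverse: reversed order from the complement */
            memcpy(wrkIn, gammaFull, m * sizeof(int));
            memset(wrkUsed, 0, m * sizeof(int));
            for (int i = 0; i < kk; i++) {
                int ii = kk - 1 - i;
                wrkIn[vars[ii]] = cState[ii];
                wrkOps[i] = cState[ii] ? OP_REMOVE : OP_ADD;
                wrkVars[i] = vars[ii];
            }
            lqR[code] = nbr_seq_logprob(st, cutoff, pNbr, kMax, wrkIn, wrkUsed,
                                        wrkOps, wrkVars, kk);
        }
    }
    int full = nSub - 1;
    double *logw = (double *) R_alloc(nSub, sizeof(double));
    double maxLogw = R_NegInf;
    for (int code = 0; code < nSub; code++) {
        int comp = code ^ full;
        double delta = logpostTab[comp] + lqR[code]
            - logpostTab[code] - lqF[code];
        logw[code] = (delta >= 0 || !R_FINITE(lqF[code])) ? R_NegInf
            : logpostTab[code] + lqF[code] + log1p(-exp(delta));
        if (logw[code] > maxLogw) maxLogw = logw[code];
    }
    if (!R_FINITE(maxLogw)) {  /* degenerate: remain at gamma */
        dr_navigate(st, curCode, 0, vars);
        rec.drUsed = 1;
        return rec;
    }
    double *wts = (double *) R_alloc(nSub, sizeof(double));
    for (int code = 0; code < nSub; code++)
        wts[code] = R_FINITE(logw[code]) ? exp(logw[code] - maxLogw) : 0.0;
    int pick = sample_prop(wts, nSub);
    dr_navigate(st, curCode, pick, vars);
    int jump = 0;
    for (int b = 0; b < kk; b++) if ((pick >> b) & 1) jump++;
    rec.jump = jump;
    rec.accepted = jump > 0;
    rec.drUsed = 1;
    if (wantDetail && R_FINITE(logw[0]))
        rec.detail = dr_detail(vars, gammaState, kk, pick,
                               logw[0], logw[pick],
                               law == 0 ? "weights" : "nbr");
    return rec;
}

/* ---------------- main sequential kernels (SS / MS / MS-DR) -------------- */

/* mode: 0 = ss, 1 = ms, 2 = msdr */
static Record main_step(MState *st, const double *addW, const double *removeW,
                        double pGeom, int kMax, int drCutoff, int mode,
                        int wantDetail, int cutoff, double pNbr)
{
    const char *kernel = mode == 0 ? "ss" : (mode == 2 ? "msdr" : "ms");
    int m = st->m;
    int singleStep = mode == 0;
    int k = (singleStep || kMax == 1) ? 1 : trunc_geom_sample(pGeom, kMax);
    Record rec = {kernel, 0, k, 0, 0, 0, 0.0, R_NilValue};

    int *work = (int *) R_alloc(m, sizeof(int));
    int *used = (int *) R_alloc(m, sizeof(int));
    int *ops = (int *) R_alloc(k, sizeof(int));
    int *vars = (int *) R_alloc(k, sizeof(int));
    memcpy(work, st->inModel, m * sizeof(int));
    memset(used, 0, m * sizeof(int));
    double logq = 0.0;
    int len = 0;
    for (int s = 0; s < k; s++) {
        int nAdd = 0, nRem = 0;
        double sumAdd = 0.0, sumRem = 0.0;
        for (int t = 0; t < m; t++) {
            if (used[t]) continue;
            if (work[t]) { nRem++; sumRem += removeW[t]; }
            else { nAdd++; sumAdd += addW[t]; }
        }
        if (nAdd == 0 && nRem == 0) break;
        int doAdd;
        if (nAdd > 0 && nRem > 0) {
            doAdd = unif_rand() < 0.5;
            logq -= M_LN2;
        } else doAdd = nAdd > 0;
        double tot = doAdd ? sumAdd : sumRem;
        double u = unif_rand() * tot, c = 0.0;
        int j = -1;
        for (int t = 0; t < m; t++) {
            if (used[t]) continue;
            if (doAdd ? work[t] : !work[t]) continue;
            c += doAdd ? addW[t] : removeW[t];
            if (u < c) { j = t; break; }
        }
        if (j < 0)  /* floating-point edge: take the last eligible */
            for (int t = m - 1; t >= 0; t--)
                if (!used[t] && (doAdd ? !work[t] : work[t])) { j = t; break; }
        logq += doAdd ? log(addW[j]) - log(sumAdd)
                      : log(removeW[j]) - log(sumRem);
        ops[len] = doAdd ? OP_ADD : OP_REMOVE;
        vars[len] = j;
        len++;
        used[j] = 1;
        work[j] = doAdd;
    }
    if (len == 0) return rec;
    int any = 0;
    for (int t = 0; t < m; t++) if (!used[t]) { any = 1; break; }
    int exhausted = !any;
    double logqFwd = logq +
        (singleStep ? 0.0 : size_log_factor(len, exhausted, pGeom, kMax));
    double logpostOld = st->logpost;
    /* apply to the live state */
    int nOk = 0;
    for (int s = 0; s < len; s++) {
        int ok = ops[s] == OP_ADD ? state_add(st, vars[s], st->tau2full[vars[s]])
                                  : (state_remove(st, vars[s]), 1);
        if (!ok) break;
        nOk++;
    }
    rec.kProposed = len;
    if (nOk < len) {  /* saturated or refused pivot: plain rejection */
        for (int s = nOk - 1; s >= 0; s--) {
            if (ops[s] == OP_ADD) state_remove(st, vars[s]);
            else if (!state_add(st, vars[s], st->tau2full[vars[s]]))
                error("internal error: pivot refused while reverting");
        }
        return rec;
    }
    /* reverse sequence log-probability from gamma' */
    int *rops = (int *) R_alloc(len, sizeof(int));
    int *rvars = (int *) R_alloc(len, sizeof(int));
    for (int s = 0; s < len; s++) {
        rops[s] = -ops[len - 1 - s];
        rvars[s] = vars[len - 1 - s];
    }
    memcpy(work, st->inModel, m * sizeof(int));
    memset(used, 0, m * sizeof(int));
    int exhR = 0;
    double stepsR = seq_steps_logprob(addW, removeW, m, work, used,
                                      rops, rvars, len, &exhR);
    double logqRev = stepsR +
        (singleStep ? 0.0 : size_log_factor(len, exhR, pGeom, kMax));
    double logA = st->logpost + logqRev - logpostOld - logqFwd;
    double a = logA >= 0 ? 1.0 : exp(logA);
    rec.accProb = a;
    if (unif_rand() < a) {
        rec.jump = len;
        rec.accepted = 1;
        return rec;
    }
    if (mode == 2 && len <= drCutoff) {
        Record drRec = dr_second_stage(st, ops, vars, len, a, addW, removeW,
                                       pGeom, kMax, cutoff, pNbr, 0,
                                       wantDetail, kernel);
        drRec.kDrawn = k;
        return drRec;
    }
    for (int s = len - 1; s >= 0; s--) {
        if (ops[s] == OP_ADD) state_remove(st, vars[s]);
        else if (!state_add(st, vars[s], st->tau2full[vars[s]]))
            error("internal error: pivot refused while reverting");
    }
    return rec;
}

/* ---------------- swap move ---------------- */

/* pick one swap sub-move: uniform over included anchors having at least one
 * eligible excluded neighbor, then uniform over those neighbors.  Returns 1
 * and fills (*iOut, *jOut, *logpOut), or 0 when none exists.  probeOnly
 * skips the draw. */
static int swap_pick(const MState *st, int cutoff, const int *used,
                     int probeOnly, int *iOut, int *jOut, double *logpOut)
{
    int q = st->q;
    int nOk = 0;
    int *okAnchor = probeOnly ? NULL : (int *) R_alloc(q > 0 ? q : 1, sizeof(int));
    for (int t = 0; t < q; t++) {
        int i = st->incl[t];
        if (used[i]) continue;
        int pos = st->orderPos[i];
        int lo = pos - cutoff; if (lo < 0) lo = 0;
        int hi = pos + cutoff; if (hi > st->m - 1) hi = st->m - 1;
        int found = 0;
        for (int s = lo; s <= hi; s++) {
            int wv = st->orderVar[s];
            if (wv != i && !st->inModel[wv] && !used[wv]) { found = 1; break; }
        }
        if (found) {
            if (probeOnly) return 1;
            okAnchor[nOk++] = i;
        }
    }
    if (nOk == 0) return 0;
    int i = okAnchor[(int) (unif_rand() * nOk) % nOk];
    int pos = st->orderPos[i];
    int lo = pos - cutoff; if (lo < 0) lo = 0;
    int hi = pos + cutoff; if (hi > st->m - 1) hi = st->m - 1;
    int nCand = 0;
    for (int s = lo; s <= hi; s++) {
        int wv = st->orderVar[s];
        if (wv != i && !st->inModel[wv] && !used[wv]) nCand++;
    }
    int pickIdx = (int) (unif_rand() * nCand) % nCand, j = -1, c = 0;
    for (int s = lo; s <= hi; s++) {
        int wv = st->orderVar[s];
        if (wv != i && !st->inModel[wv] && !used[wv]) {
            if (c == pickIdx) { j = wv; break; }
            c++;
        }
    }
    *iOut = i; *jOut = j;
    *logpOut = -log((double) nOk) - log((double) nCand);
    return 1;
}

/* reverse log-probability of a swap sequence, replayed on a virtual
 * configuration starting from gamma' */
static double swap_seq_logprob(const MState *st, int cutoff, double pSwap,
                               int kMax, const int (*pairs)[2], int len)
{
    int m = st->m;
    int *inModel = (int *) R_alloc(m, sizeof(int));
    int *used = (int *) R_alloc(m, sizeof(int));
    memcpy(inModel, st->inModel, m * sizeof(int));
    memset(used, 0, m * sizeof(int));
    double logq = 0.0;
    for (int t = len - 1; t >= 0; t--) {
        int i = pairs[t][1], j = pairs[t][0];  /* reverse swap: j' -> i' */
        int okCount = 0, candCount = 0;
        for (int v = 0; v < m; v++) {
            if (!inModel[v] || used[v]) continue;
            int pos = st->orderPos[v];
            int lo = pos - cutoff; if (lo < 0) lo = 0;
            int hi = pos + cutoff; if (hi > m - 1) hi = m - 1;
            int nNb = 0;
            for (int s = lo; s <= hi; s++) {
                int wv = st->orderVar[s];
                if (wv != v && !inModel[wv] && !used[wv]) nNb++;
            }
            if (nNb > 0) {
                okCount++;
                if (v == i) candCount = nNb;
            }
        }
        if (okCount == 0 || candCount == 0) return R_NegInf;
        logq += -log((double) okCount) - log((double) candCount);
        inModel[i] = 0; inModel[j] = 1;
        used[i] = 1; used[j] = 1;
    }
    /* tail factor for the reverse direction */
    int more = 0;
    for (int v = 0; v < m && !more; v++) {
        if (!inModel[v] || used[v]) continue;
        int pos = st->orderPos[v];
        int lo = pos - cutoff; if (lo < 0) lo = 0;
        int hi = pos + cutoff; if (hi > m - 1) hi = m - 1;
        for (int s = lo; s <= hi; s++) {
            int wv = st->orderVar[s];
            if (wv != v && !inModel[wv] && !used[wv]) { more = 1; break; }
        }
    }
    return logq + size_log_factor(len, !more, pSwap, kMax);
}

static Record swap_step(MState *st, int cutoff, double pSwap, int kMax)
{
    Record rec = {"swap", 0, 0, 0, 0, 0, 0.0, R_NilValue};
    double logpostOld = st->logpost;
    int k = trunc_geom_sample(pSwap, kMax);
    int m = st->m;
    int *used = (int *) R_alloc(m, sizeof(int));
    memset(used, 0, m * sizeof(int));
    int (*pairs)[2] = (int (*)[2]) R_alloc(k, 2 * sizeof(int));
    double logqFwd = 0.0;
    int len = 0;
    for (int s = 0; s < k; s++) {
        int i, j;
        double logp;
        if (!swap_pick(st, cutoff, used, 0, &i, &j, &logp)) break;
        state_remove(st, i);
        if (!state_add(st, j, st->tau2full[j])) {
            if (!state_add(st, i, st->tau2full[i]))
                error("internal error: pivot refused while reverting");
            break;
        }
        logqFwd += logp;
        used[i] = 1; used[j] = 1;
        pairs[len][0] = i; pairs[len][1] = j;
        len++;
    }
    if (len == 0) return rec;
    rec.kProposed = 2 * len;
    int iDummy, jDummy; double lpDummy;
    int more = swap_pick(st, cutoff, used, 1, &iDummy, &jDummy, &lpDummy);
    logqFwd += size_log_factor(len, !more, pSwap, kMax);
    double logqRev = swap_seq_logprob(st, cutoff, pSwap, kMax,
                                      (const int (*)[2]) pairs, len);
    double logA = st->logpost + logqRev - logpostOld - logqFwd;
    double a = logA >= 0 ? 1.0 : exp(logA);
    rec.accProb = a;
    if (unif_rand() < a) {
        rec.jump = 2 * len;
        rec.accepted = 1;
        return rec;
    }
    for (int t = len - 1; t >= 0; t--) {  /* undo swaps in reverse order */
        state_remove(st, pairs[t][1]);
        if (!state_add(st, pairs[t][0], st->tau2full[pairs[t][0]]))
            error("internal error: pivot refused while reverting");
    }
    return rec;
}

/* ---------------- neighborhood toggle move ---------------- */

static Record nbr_step(MState *st, int cutoff, double pNbr, int kMax, int dr,
                       int drCutoff, const double *addW, const double *removeW,
                       double pGeom, int wantDetail)
{
    Record rec = {"nbr", 0, 0, 0, 0, 0, 0.0, R_NilValue};
    double logpostOld = st->logpost;
    int k = trunc_geom_sample(pNbr, kMax);
    int m = st->m;
    int *used = (int *) R_alloc(m, sizeof(int));
    memset(used, 0, m * sizeof(int));
    int *ops = (int *) R_alloc(k, sizeof(int));
    int *vars = (int *) R_alloc(k, sizeof(int));
    double logqFwd = 0.0;
    int len = 0;
    for (int s = 0; s < k; s++) {
        int total = nbr_pairs(st, cutoff, st->inModel, used, -1, NULL, -1, NULL);
        if (total == 0) break;
        int idx = (int) (unif_rand() * total) % total;
        int v = -1, cnt = 0;
        nbr_pairs(st, cutoff, st->inModel, used, idx, &v, -1, NULL);
        /* the forward factor is evaluated at the pre-toggle configuration */
        nbr_pairs(st, cutoff, st->inModel, used, -1, NULL, v, &cnt);
        int doAdd = !st->inModel[v];
        int ok = doAdd ? state_add(st, v, st->tau2full[v])
                       : (state_remove(st, v), 1);
        if (!ok) break;
        logqFwd += log((double) cnt) - log((double) total);
        ops[len] = doAdd ? OP_ADD : OP_REMOVE;
        vars[len] = v;
        len++;
        used[v] = 1;
    }
    if (len == 0) return rec;
    rec.kProposed = len;
    int more = nbr_pairs(st, cutoff, st->inModel, used, -1, NULL, -1, NULL) > 0;
    logqFwd += size_log_factor(len, !more, pNbr, kMax);
    /* reverse replay from gamma' */
    int *rops = (int *) R_alloc(len, sizeof(int));
    int *rvars = (int *) R_alloc(len, sizeof(int));
    for (int s = 0; s < len; s++) {
        rops[s] = -ops[len - 1 - s];
        rvars[s] = vars[len - 1 - s];
    }
    int *wrkIn = (int *) R_alloc(m, sizeof(int));
    int *wrkUsed = (int *) R_alloc(m, sizeof(int));
    memcpy(wrkIn, st->inModel, m * sizeof(int));
    memset(wrkUsed, 0, m * sizeof(int));
    double logqRev = nbr_seq_logprob(st, cutoff, pNbr, kMax, wrkIn, wrkUsed,
                                     rops, rvars, len);
    double logA = st->logpost + logqRev - logpostOld - logqFwd;
    double a = logA >= 0 ? 1.0 : exp(logA);
    rec.accProb = a;
    if (unif_rand() < a) {
        rec.jump = len;
        rec.accepted = 1;
        return rec;
    }
    if (dr && len <= drCutoff) {
        Record drRec = dr_second_stage(st, ops, vars, len, a, addW, removeW,
                                       pGeom, kMax, cutoff, pNbr, 1,
                                       wantDetail, "nbr");
        return drRec;
    }
    for (int s = len - 1; s >= 0; s--) {
        if (ops[s] == OP_ADD) state_remove(st, vars[s]);
        else if (!state_add(st, vars[s], st->tau2full[vars[s]]))
            error("internal error: pivot refused while reverting");
    }
    return rec;
}

/* ---------------- comparison kernels ---------------- */

static Record ksc_step(MState *st, int blockK)
{
    Record rec = {"ksc", 0, 0, 0, 0, 0, 0.0, R_NilValue};
    int m = st->m;
    int kk = blockK < m ? blockK : m;
    /* kk distinct uniform variants (partial Fisher-Yates) */
    int *idx = (int *) R_alloc(m, sizeof(int));
    for (int t = 0; t < m; t++) idx[t] = t;
    int *K = (int *) R_alloc(kk, sizeof(int));
    for (int t = 0; t < kk; t++) {
        int r = t + (int) (unif_rand() * (m - t)) % (m - t);
        int tmp = idx[t]; idx[t] = idx[r]; idx[r] = tmp;
        K[t] = idx[t];
    }
    int qOut = st->q, curCode = 0;
    for (int t = 0; t < kk; t++)
        if (st->inModel[K[t]]) { qOut--; curCode |= 1 << t; }
    int nSub = 1 << kk;
    double *lp = (double *) R_alloc(nSub, sizeof(double));
    double maxLp = R_NegInf;
    for (int code = 0; code < nSub; code++) {
        int sz = qOut;
        for (int b = 0; b < kk; b++) if ((code >> b) & 1) sz++;
        lp[code] = st->priorTab[sz];
        if (lp[code] > maxLp) maxLp = lp[code];
    }
    double *pr = (double *) R_alloc(nSub, sizeof(double));
    for (int code = 0; code < nSub; code++) pr[code] = exp(lp[code] - maxLp);
    int pick = sample_prop(pr, nSub);
    int nFlip = 0;
    int *fOps = (int *) R_alloc(kk, sizeof(int));
    int *fVars = (int *) R_alloc(kk, sizeof(int));
    for (int t = 0; t < kk; t++) {
        int now = (curCode >> t) & 1, nw = (pick >> t) & 1;
        if (now != nw) {
            fOps[nFlip] = now ? OP_REMOVE : OP_ADD;
            fVars[nFlip] = K[t];
            nFlip++;
        }
    }
    if (nFlip == 0) { rec.accProb = 1.0; return rec; }
    rec.kProposed = nFlip;
    double logpostOld = st->logpost;
    int nOk = 0;
    for (int s = 0; s < nFlip; s++) {
        int ok = fOps[s] == OP_ADD
            ? state_add(st, fVars[s], st->tau2full[fVars[s]])
            : (state_remove(st, fVars[s]), 1);
        if (!ok) break;
        nOk++;
    }
    if (nOk < nFlip) {
        for (int s = nOk - 1; s >= 0; s--) {
            if (fOps[s] == OP_ADD) state_remove(st, fVars[s]);
            else if (!state_add(st, fVars[s], st->tau2full[fVars[s]]))
                error("internal error: pivot refused while reverting");
        }
        return rec;
    }
    /* forward and reverse proposal probabilities share the normalizer */
    double logA = st->logpost + lp[curCode] - logpostOld - lp[pick];
    double a = logA >= 0 ? 1.0 : exp(logA);
    rec.accProb = a;
    if (unif_rand() < a) {
        rec.jump = nFlip;
        rec.accepted = 1;
        return rec;
    }
    for (int s = nFlip - 1; s >= 0; s--) {
        if (fOps[s] == OP_ADD) state_remove(st, fVars[s]);
        else if (!state_add(st, fVars[s], st->tau2full[fVars[s]]))
            error("internal error: pivot refused while reverting");
    }
    return rec;
}

static Record nk_step(MState *st, int blockK, const double *pipHat,
                      double epsMin)
{
    Record rec = {"nk", 0, 0, 0, 0, 0, 0.0, R_NilValue};
    int m = st->m;
    int kk = blockK < m ? blockK : m;
    int *idx = (int *) R_alloc(m, sizeof(int));
    for (int t = 0; t < m; t++) idx[t] = t;
    int *K = (int *) R_alloc(kk, sizeof(int));
    for (int t = 0; t < kk; t++) {
        int r = t + (int) (unif_rand() * (m - t)) % (m - t);
        int tmp = idx[t]; idx[t] = idx[r]; idx[r] = tmp;
        K[t] = idx[t];
    }
    double logqFwd = 0.0, logqRev = 0.0;
    int nFlip = 0;
    int *fOps = (int *) R_alloc(kk, sizeof(int));
    int *fVars = (int *) R_alloc(kk, sizeof(int));
    for (int t = 0; t < kk; t++) {
        double p = pipHat[K[t]];
        if (p < epsMin) p = epsMin;
        if (p > 1 - epsMin) p = 1 - epsMin;
        int cur = st->inModel[K[t]];
        int nw = unif_rand() < p;
        logqFwd += nw ? log(p) : log1p(-p);
        logqRev += cur ? log(p) : log1p(-p);
        if (nw != cur) {
            fOps[nFlip] = cur ? OP_REMOVE : OP_ADD;
            fVars[nFlip] = K[t];
            nFlip++;
        }
    }
    if (nFlip == 0) { rec.accProb = 1.0; return rec; }
    rec.kProposed = nFlip;
    double logpostOld = st->logpost;
    int nOk = 0;
    for (int s = 0; s < nFlip; s++) {
        int ok = fOps[s] == OP_ADD
            ? state_add(st, fVars[s], st->tau2full[fVars[s]])
            : (state_remove(st, fVars[s]), 1);
        if (!ok) break;
        nOk++;
    }
    if (nOk < nFlip) {
        for (int s = nOk - 1; s >= 0; s--) {
            if (fOps[s] == OP_ADD) state_remove(st, fVars[s]);
            else if (!state_add(st, fVars[s], st->tau2full[fVars[s]]))
                error("internal error: pivot refused while reverting");
        }
        return rec;
    }
    double logA = st->logpost + logqRev - logpostOld - logqFwd;
    double a = logA >= 0 ? 1.0 : exp(logA);
    rec.accProb = a;
    if (unif_rand() < a) {
        rec.jump = nFlip;
        rec.accepted = 1;
        return rec;
    }
    for (int s = nFlip - 1; s >= 0; s--) {
        if (fOps[s] == OP_ADD) state_remove(st, fVars[s]);
        else if (!state_add(st, fVars[s], st->tau2full[fVars[s]]))
            error("internal error: pivot refused while reverting");
    }
    return rec;
}

/* ---------------- .Call interface ---------------- */

SEXP C_state_new(SEXP Xs, SEXP ys, SEXP colSqs, SEXP aPis, SEXP bPis,
                 SEXP nuSigmas, SEXP s2Sigmas, SEXP orderPosS,
                 SEXP refactorS)
{
    int n = Rf_nrows(Xs), m = Rf_ncols(Xs);
    MState *st = calloc(1, sizeof(MState));
    if (!st) error("out of memory");
    st->n = n; st->m = m;
    st->X = malloc((size_t) n * m * sizeof(double));
    st->y = malloc(n * sizeof(double));
    st->Xty = malloc(m * sizeof(double));
    st->colSq = malloc(m * sizeof(double));
    st->priorTab = malloc((m + 1) * sizeof(double));
    st->tau2full = malloc(m * sizeof(double));
    st->orderPos = malloc(m * sizeof(int));
    st->orderVar = malloc(m * sizeof(int));
    int cap = 16;
    if (cap > n) cap = n;
    st->cap = cap;
    st->R = calloc((size_t) cap * cap, sizeof(double));
    st->scrA = calloc((size_t) cap * cap, sizeof(double));
    st->w = calloc(cap, sizeof(double));
    st->tau2incl = calloc(cap, sizeof(double));
    st->scrV = calloc(cap, sizeof(double));
    st->incl = calloc(cap, sizeof(int));
    st->inModel = calloc(m, sizeof(int));
    if (!st->X || !st->y || !st->Xty || !st->colSq || !st->priorTab ||
        !st->tau2full || !st->orderPos || !st->orderVar || !st->R ||
        !st->scrA || !st->w || !st->tau2incl || !st->scrV || !st->incl ||
        !st->inModel)
        error("out of memory");
    memcpy(st->X, REAL(Xs), (size_t) n * m * sizeof(double));
    memcpy(st->y, REAL(ys), n * sizeof(double));
    memcpy(st->colSq, REAL(colSqs), m * sizeof(double));
    st->yty = 0.0;
    for (int i = 0; i < n; i++) st->yty += st->y[i] * st->y[i];
    for (int j = 0; j < m; j++) {
        double s = 0.0;
        const double *xc = st->X + (size_t) j * n;
        for (int i = 0; i < n; i++) s += xc[i] * st->y[i];
        st->Xty[j] = s;
        st->tau2full[j] = 1.0;
        st->orderPos[j] = INTEGER(orderPosS)[j] - 1;
        st->orderVar[st->orderPos[j]] = j;
    }
    double aPi = Rf_asReal(aPis), bPi = Rf_asReal(bPis);
    double nu = Rf_asReal(nuSigmas), s2 = Rf_asReal(s2Sigmas);
    st->nuSigma = nu; st->s2Sigma = s2;
    st->mlConst = lgammafn((nu + n - 1) / 2.0) - lgammafn(nu / 2.0)
        - ((n - 1) / 2.0) * log(M_PI * nu * s2);
    st->mlCoef = (nu + n - 1) / 2.0;
    double lb0 = lbeta(aPi, bPi);
    for (int q = 0; q <= m; q++)
        st->priorTab[q] = lbeta(aPi + q, bPi + m - q) - lb0;
    st->refactorInterval = Rf_asInteger(refactorS);
    st->q = 0; st->nMods = 0;
    st->sumLogTau2 = 0.0; st->sumLogDiagR = 0.0;
    state_recache(st);
    SEXP ptr = PROTECT(R_MakeExternalPtr(st, R_NilValue, R_NilValue));
    R_RegisterCFinalizerEx(ptr, state_free, TRUE);
    UNPROTECT(1);
    return ptr;
}

SEXP C_state_set_tau2(SEXP ptr, SEXP tau2s)
{
    MState *st = state_get(ptr);
    if (Rf_length(tau2s) != st->m) error("tau2 length mismatch");
    memcpy(st->tau2full, REAL(tau2s), st->m * sizeof(double));
    for (int t = 0; t < st->q; t++)
        st->tau2incl[t] = st->tau2full[st->incl[t]];
    state_refactor(st);
    state_recache(st);
    return R_NilValue;
}

SEXP C_state_info(SEXP ptr)
{
    MState *st = state_get(ptr);
    const char *names[] = {"q", "incl", "logpost", "logml", "S", ""};
    SEXP out = PROTECT(Rf_mkNamed(VECSXP, names));
    SET_VECTOR_ELT(out, 0, Rf_ScalarInteger(st->q));
    SEXP incl = PROTECT(Rf_allocVector(INTSXP, st->q));
    for (int t = 0; t < st->q; t++) INTEGER(incl)[t] = st->incl[t] + 1;
    SET_VECTOR_ELT(out, 1, incl);
    SET_VECTOR_ELT(out, 2, Rf_ScalarReal(st->logpost));
    SET_VECTOR_ELT(out, 3, Rf_ScalarReal(st->logml));
    double S = st->yty;
    for (int i = 0; i < st->q; i++) S -= st->w[i] * st->w[i];
    SET_VECTOR_ELT(out, 4, Rf_ScalarReal(S));
    UNPROTECT(2);
    return out;
}

SEXP C_state_add(SEXP ptr, SEXP js, SEXP tau2s)
{
    MState *st = state_get(ptr);
    int j = Rf_asInteger(js) - 1;
    if (j < 0 || j >= st->m) error("variant index out of range");
    if (st->inModel[j]) error("variant already included");
    return Rf_ScalarLogical(state_add(st, j, Rf_asReal(tau2s)));
}

SEXP C_state_remove(SEXP ptr, SEXP js)
{
    MState *st = state_get(ptr);
    int j = Rf_asInteger(js) - 1;
    if (j < 0 || j >= st->m) error("variant index out of range");
    if (!st->inModel[j]) error("variant not included");
    state_remove(st, j);
    return R_NilValue;
}

/* draw the included coefficients beta_gamma ~ N(A^{-1} X'y, sigma2 A^{-1}) */
SEXP C_beta_draw(SEXP ptr, SEXP sigma2s)
{
    MState *st = state_get(ptr);
    int q = st->q, cap = st->cap;
    double sigma = sqrt(Rf_asReal(sigma2s));
    SEXP out = PROTECT(Rf_allocVector(REALSXP, q));
    if (q > 0) {
        double *mu = (double *) R_alloc(q, sizeof(double));
        double *z = (double *) R_alloc(q, sizeof(double));
        GetRNGstate();
        for (int i = 0; i < q; i++) z[i] = norm_rand();
        PutRNGstate();
        /* mu = R^{-1} w, t = R^{-1} z (back substitution) */
        for (int i = q - 1; i >= 0; i--) {
            double smu = st->w[i], sz = z[i];
            for (int k2 = i + 1; k2 < q; k2++) {
                smu -= st->R[i + (size_t) k2 * cap] * mu[k2];
                sz -= st->R[i + (size_t) k2 * cap] * REAL(out)[k2];
            }
            mu[i] = smu / st->R[i + (size_t) i * cap];
            REAL(out)[i] = sz / st->R[i + (size_t) i * cap];
        }
        for (int i = 0; i < q; i++) REAL(out)[i] = mu[i] + sigma * REAL(out)[i];
    }
    UNPROTECT(1);
    return out;
}

SEXP C_main_step(SEXP ptr, SEXP addWs, SEXP removeWs, SEXP pGeoms,
                 SEXP kMaxs, SEXP drCutoffs, SEXP modes, SEXP wantDetails,
                 SEXP cutoffs, SEXP pNbrs)
{
    MState *st = state_get(ptr);
    if (Rf_length(addWs) != st->m || Rf_length(removeWs) != st->m)
        error("weight length mismatch");
    GetRNGstate();
    Record rec = main_step(st, REAL(addWs), REAL(removeWs), Rf_asReal(pGeoms),
                           Rf_asInteger(kMaxs), Rf_asInteger(drCutoffs),
                           Rf_asInteger(modes), Rf_asLogical(wantDetails),
                           Rf_asInteger(cutoffs), Rf_asReal(pNbrs));
    PutRNGstate();
    SEXP out = PROTECT(record_to_sexp(&rec));
    UNPROTECT(rec.detail == R_NilValue ? 1 : 2);  /* out (+ detail) */
    return out;
}

SEXP C_swap_step(SEXP ptr, SEXP cutoffs, SEXP pSwaps, SEXP kMaxs)
{
    MState *st = state_get(ptr);
    GetRNGstate();
    Record rec = swap_step(st, Rf_asInteger(cutoffs), Rf_asReal(pSwaps),
                           Rf_asInteger(kMaxs));
    PutRNGstate();
    return record_to_sexp(&rec);
}

SEXP C_nbr_step(SEXP ptr, SEXP cutoffs, SEXP pNbrs, SEXP kMaxs, SEXP drs,
                SEXP drCutoffs, SEXP addWs, SEXP removeWs, SEXP pGeoms,
                SEXP wantDetails)
{
    MState *st = state_get(ptr);
    GetRNGstate();
    Record rec = nbr_step(st, Rf_asInteger(cutoffs), Rf_asReal(pNbrs),
                          Rf_asInteger(kMaxs), Rf_asLogical(drs),
                          Rf_asInteger(drCutoffs), REAL(addWs),
                          REAL(removeWs), Rf_asReal(pGeoms),
                          Rf_asLogical(wantDetails));
    PutRNGstate();
    SEXP out = PROTECT(record_to_sexp(&rec));
    UNPROTECT(rec.detail == R_NilValue ? 1 : 2);  /* out (+ detail) */
    return out;
}

SEXP C_ksc_step(SEXP ptr, SEXP blockKs)
{
    MState *st = state_get(ptr);
    GetRNGstate();
    Record rec = ksc_step(st, Rf_asInteger(blockKs));
    PutRNGstate();
    return record_to_sexp(&rec);
}

SEXP C_nk_step(SEXP ptr, SEXP blockKs, SEXP pipHats, SEXP epsMins)
{
    MState *st = state_get(ptr);
    if (Rf_length(pipHats) != st->m) error("pipHat length mismatch");
    GetRNGstate();
    Record rec = nk_step(st, Rf_asInteger(blockKs), REAL(pipHats),
                         Rf_asReal(epsMins));
    PutRNGstate();
    return record_to_sexp(&rec);
}

/* ---------------- registration ---------------- */

static const R_CallMethodDef CallEntries[] = {
    {"C_state_new", (DL_FUNC) &C_state_new, 9},
    {"C_state_set_tau2", (DL_FUNC) &C_state_set_tau2, 2},
    {"C_state_info", (DL_FUNC) &C_state_info, 1},
    {"C_state_add", (DL_FUNC) &C_state_add, 3},
    {"C_state_remove", (DL_FUNC) &C_state_remove, 2},
    {"C_beta_draw", (DL_FUNC) &C_beta_draw, 2},
    {"C_main_step", (DL_FUNC) &C_main_step, 10},
    {"C_swap_step", (DL_FUNC) &C_swap_step, 4},
    {"C_nbr_step", (DL_FUNC) &C_nbr_step, 10},
    {"C_ksc_step", (DL_FUNC) &C_ksc_step, 2},
    {"C_nk_step", (DL_FUNC) &C_nk_step, 4},
    {NULL, NULL, 0}
};

void R_init_SpikeSlabGWAS(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
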