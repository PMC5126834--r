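#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Dynamic programming for profile-HMM alignment in log2-odds space.
//
// Conventions shared by both entry points:
//  - seq: 0-based residue codes; code >= 20 is an ambiguity code and scores 0
//    (matrices carry a 21st zero column, so no branch is needed).
//  - mat, ins: L x 21 matrices of log2(emission/background) scores.
//  - transition vectors have length L; index k (0-based) holds the score of
//    the transition leaving model position k+1 towards position k+2; the last
//    entry is unused (exit is handled by the mode's topology).
//  - Flanking (and, in local mode, inter-domain) residues score 0: the null
//    model emits them at background frequency, so their log-odds cancel.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Glocal: the path must traverse model positions 1..L exactly once through
// match or delete states; entry only at position 1 (B->M1 or B->D1), exit
// only after position L (free).
// [[Rcpp::export(name = ".viterbi_glocal_cpp")]]
List viterbi_glocal_cpp(IntegerVector seq, NumericMatrix mat, NumericMatrix ins,
                        NumericVector tMM, NumericVector tMI, NumericVector tMD,
                        NumericVector tIM, NumericVector tII,
                        NumericVector tDM, NumericVector tDD,
                        double log_bm, double log_bd) {
  const int n = seq.size(), L = mat.nrow();
  if (L < 1) stop("model has no match positions");

  NumericMatrix VM(n + 1, L), VI(n + 1, L), VD(n + 1, L);
  IntegerMatrix PM(n + 1, L), PI(n + 1, L), PD(n + 1, L);
  std::fill(VM.begin(), VM.end(), NEG_INF);
  std::fill(VI.begin(), VI.end(), NEG_INF);
  std::fill(VD.begin(), VD.end(), NEG_INF);
  // pointer codes: 0 = entry (B), 1 = from M, 2 = from I, 3 = from D

  for (int j = 0; j <= n; ++j) {
    for (int k = 0; k < L; ++k) {
      if (j >= 1) {
        const int x = seq[j - 1];
        // match state
        double best; int ptr;
        if (k == 0) { best = log_bm; ptr = 0; }
        else {
          best = VM(j - 1, k - 1) + tMM[k - 1]; ptr = 1;
          double c = VI(j - 1, k - 1) + tIM[k - 1];
          if (c > best) { best = c; ptr = 2; }
          c = VD(j - 1, k - 1) + tDM[k - 1];
          if (c > best) { best = c; ptr = 3; }
        }
        VM(j, k) = mat(k, x) + best;
        PM(j, k) = ptr;
        // insert state I_k sits between positions k+1 and k+2
        if (k < L - 1) {
          double bi = VM(j - 1, k) + tMI[k]; int pi = 1;
          double ci = VI(j - 1, k) + tII[k];
          if (ci > bi) { bi = ci; pi = 2; }
          VI(j, k) = ins(k, x) + bi;
          PI(j, k) = pi;
        }
      }
      // delete state (no residue consumed)
      if (k == 0) { VD(j, 0) = log_bd; PD(j, 0) = 0; }
      else {
        double bd = VM(j, k - 1) + tMD[k - 1]; int pd = 1;
        double cd = VD(j, k - 1) + tDD[k - 1];
        if (cd > bd) { bd = cd; pd = 3; }
        VD(j, k) = bd;
        PD(j, k) = pd;
      }
    }
  }

  // termination: free exit from M_L or D_L; trailing residues are flank
  double best = NEG_INF; int best_j = 0, best_state = 1; // 1 = M, 3 = D
  for (int j = 0; j <= n; ++j) {
    if (VM(j, L - 1) > best) { best = VM(j, L - 1); best_j = j; best_state = 1; }
    if (VD(j, L - 1) > best) { best = VD(j, L - 1); best_j = j; best_state = 3; }
  }

  // traceback; glocal visits each model column exactly once via M or D
  IntegerVector col_state(L), col_res(L);   // 1 = M, 2 = D; residue index (1-based) or 0
  NumericVector emis(L), trans(L > 1 ? L - 1 : 0);
  double entry_score = 0.0;
  int j = best_j, k = L - 1, state = best_state;
  while (true) {
    if (state == 1) { // match
      col_state[k] = 1; col_res[k] = j; emis[k] = mat(k, seq[j - 1]);
      int ptr = PM(j, k);
      if (ptr == 0) { entry_score = log_bm; break; }
      if (ptr == 1) { trans[k - 1] = tMM[k - 1]; --j; --k; state = 1; }
      else if (ptr == 3) { trans[k - 1] = tDM[k - 1]; --j; --k; state = 3; }
      else { // insert run between k-1 and k
        double t = tIM[k - 1];
        int jj = j - 1;
        while (PI(jj, k - 1) == 2) { t += ins(k - 1, seq[jj - 1]) + tII[k - 1]; --jj; }
        t += ins(k - 1, seq[jj - 1]) + tMI[k - 1];
        trans[k - 1] = t;
        j = jj - 1; --k; state = 1;
      }
    } else { // delete
      col_state[k] = 2; col_res[k] = 0; emis[k] = 0.0;
      int ptr = PD(j, k);
      if (ptr == 0) { entry_score = log_bd; break; }
      if (ptr == 1) { trans[k - 1] = tMD[k - 1]; --k; state = 1; }
      else { trans[k - 1] = tDD[k - 1]; --k; state = 3; }
    }
  }

  int seq_from = 0, seq_to = 0;
  for (int c = 0; c < L; ++c)
    if (col_res[c] > 0) { if (seq_from == 0) seq_from = col_res[c]; seq_to = col_res[c]; }

  return List::create(
    _["score"] = best, _["seq_from"] = seq_from, _["seq_to"] = seq_to,
    _["col_state"] = col_state, _["col_res"] = col_res,
    _["emis"] = emis, _["trans"] = trans,
    _["entry_score"] = entry_score, _["exit_score"] = 0.0);
}

// Multihit local: entry to any match state (log_entry each), free exit after
// any match state, restart between domains costs log_loop. Deletes are
// internal only. Returns zero or more domains; total score includes the
// (d - 1) * log_loop restart terms.
// [[Rcpp::export(name = ".viterbi_local_cpp")]]
List viterbi_local_cpp(IntegerVector seq, NumericMatrix mat, NumericMatrix ins,
                       NumericVector tMM, NumericVector tMI, NumericVector tMD,
                       NumericVector tIM, NumericVector tII,
                       NumericVector tDM, NumericVector tDD,
                       double log_entry, double log_loop) {
  const int n = seq.size(), L = mat.nrow();
  if (L < 1) stop("model has no match positions");

  NumericMatrix VM(n + 1, L), VI(n + 1, L), VD(n + 1, L);
  IntegerMatrix PM(n + 1, L), PI(n + 1, L), PD(n + 1, L);
  std::fill(VM.begin(), VM.end(), NEG_INF);
  std::fill(VI.begin(), VI.end(), NEG_INF);
  std::fill(VD.begin(), VD.end(), NEG_INF);
  NumericVector VE(n + 1, NEG_INF), VJ(n + 1, NEG_INF), VB(n + 1);
  IntegerVector Earg(n + 1, -1), PJ(n + 1, -1); // PJ: 0 = from J(j-1), 1 = from E(j)
  VB[0] = 0.0;

  for (int j = 0; j <= n; ++j) {
    if (j >= 1) {
      const int x = seq[j - 1];
      for (int k = 0; k < L; ++k) {
        double best = VB[j - 1] + log_entry; int ptr = 0;
        if (k >= 1) {
          double c = VM(j - 1, k - 1) + tMM[k - 1];
          if (c > best) { best = c; ptr = 1; }
          c = VI(j - 1, k - 1) + tIM[k - 1];
          if (c > best) { best = c; ptr = 2; }
          c = VD(j - 1, k - 1) + tDM[k - 1];
          if (c > best) { best = c; ptr = 3; }
        }
        VM(j, k) = mat(k, x) + best;
        PM(j, k) = ptr;
        if (k < L - 1) {
          double bi = VM(j - 1, k) + tMI[k]; int pi = 1;
          double ci = VI(j - 1, k) + tII[k];
          if (ci > bi) { bi = ci; pi = 2; }
          VI(j, k) = ins(k, x) + bi;
          PI(j, k) = pi;
        }
        if (k >= 1) {
          double bd = VM(j, k - 1) + tMD[k - 1]; int pd = 1;
          double cd = VD(j, k - 1) + tDD[k - 1];
          if (cd > bd) { bd = cd; pd = 3; }
          VD(j, k) = bd;
          PD(j, k) = pd;
        }
      }
      // free exit from any match state
      for (int k = 0; k < L; ++k)
        if (VM(j, k) > VE[j]) { VE[j] = VM(j, k); Earg[j] = k; }
    }
    if (j >= 1) {
      VJ[j] = VJ[j - 1]; PJ[j] = 0;
      if (VE[j] + log_loop > VJ[j]) { VJ[j] = VE[j] + log_loop; PJ[j] = 1; }
      VB[j] = VJ[j] > 0.0 ? VJ[j] : 0.0;
    }
  }

  double total = 0.0; int best_j = -1;
  double best_raw = NEG_INF; // best single-exit score, not truncated at 0:
                             // the continuous score statistic used for
                             // null calibration
  for (int j = 1; j <= n; ++j) {
    if (VE[j] > total) { total = VE[j]; best_j = j; }
    if (VE[j] > best_raw) best_raw = VE[j];
  }

  List domains;
  if (best_j >= 1) {
    std::vector<List> doms;
    int j = best_j;
    while (j >= 1) {
      // walk one domain back from its final match at (j, Earg[j])
      int k = Earg[j], state = 1;
      const int model_to = k + 1, seq_to = j;
      std::vector<double> demis, dtrans;
      double dscore = 0.0;
      int model_from = 1, seq_from = 1;
      bool done = false;
      while (!done) {
        if (state == 1) {
          demis.push_back(mat(k, seq[j - 1]));
          int ptr = PM(j, k);
          if (ptr == 0) {
            dscore = log_entry; model_from = k + 1; seq_from = j; --j; done = true;
          } else if (ptr == 1) { dtrans.push_back(tMM[k - 1]); --j; --k; }
          else if (ptr == 3) { dtrans.push_back(tDM[k - 1]); --j; --k; state = 3; }
          else {
            double t = tIM[k - 1];
            int jj = j - 1;
            while (PI(jj, k - 1) == 2) { t += ins(k - 1, seq[jj - 1]) + tII[k - 1]; --jj; }
            t += ins(k - 1, seq[jj - 1]) + tMI[k - 1];
            dtrans.push_back(t);
            j = jj - 1; --k;
          }
        } else { // internal delete
          demis.push_back(0.0);
          int ptr = PD(j, k);
          if (ptr == 1) { dtrans.push_back(tMD[k - 1]); --k; state = 1; }
          else { dtrans.push_back(tDD[k - 1]); --k; }
        }
      }
      std::reverse(demis.begin(), demis.end());
      std::reverse(dtrans.begin(), dtrans.end());
      for (double e : demis) dscore += e;
      for (double t : dtrans) dscore += t;
      doms.push_back(List::create(
        _["seq_from"] = seq_from, _["seq_to"] = seq_to,
        _["model_from"] = model_from, _["model_to"] = model_to,
        _["score"] = dscore,
        _["emis"] = NumericVector(demis.begin(), demis.end()),
        _["trans"] = NumericVector(dtrans.begin(), dtrans.end()),
        _["entry_score"] = log_entry, _["exit_score"] = 0.0));
      // did this domain start from N (fresh) or from J (previous domain)?
      if (VB[j] > 0.0) {
        // came through J: locate the previous domain's end
        int jj = j;
        while (PJ[jj] == 0) --jj;
        j = jj; // VE[jj] ended the previous domain
      } else break;
    }
    std::reverse(doms.begin(), doms.end());
    domains = wrap(doms);
  } else {
    domains = List::create();
  }

  return List::create(_["score"] = total, _["best_raw"] = best_raw,
                      _["n_domains"] = domains.size(),
                      _["domains"] = domains);
}
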