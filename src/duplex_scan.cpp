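#include <Rcpp.h>
using namespace Rcpp;

// Position-weighted miRNA:target complementarity scan.
//
// The miRNA (5'->3') is aligned antiparallel against every window of the
// transcript: miRNA position 1 pairs the 3'-most base of the site.  Per
// position penalties (match / G:U wobble / mismatch / gap) are doubled
// inside the seed region (miRNA positions seed_start..seed_end) and summed
// into an "expectation"; at most `max_gaps` (0 or 1) gap is allowed.  All
// windows with expectation <= max_expectation are reported with their
// alignment strings; overlap deduplication happens in R.

static const double INF = 1e18;

// 0 = Watson-Crick match, 1 = G:U wobble, 2 = mismatch
static int pair_state(char mir, char tgt) {
  switch (mir) {
  case 'A': return tgt == 'T' ? 0 : 2;
  case 'C': return tgt == 'G' ? 0 : 2;
  case 'G': return tgt == 'C' ? 0 : (tgt == 'T' ? 1 : 2);
  case 'T': return tgt == 'A' ? 0 : (tgt == 'G' ? 1 : 2);
  default:  return 2;
  }
}

// [[Rcpp::export(name = "scan_duplex_cpp")]]
DataFrame scan_duplex(std::string mirna, std::string transcript,
                      double p_match, double p_gu, double p_mm, double p_gap,
                      int seed_start, int seed_end, double seed_mult,
                      int max_gaps, double max_expectation) {
  const int m = mirna.size();
  const int L = transcript.size();
  const double pair_pen[3] = {p_match, p_gu, p_mm};
  const bool gaps = max_gaps > 0;

  std::vector<int> out_start, out_end, out_gaps;
  std::vector<double> out_exp;
  std::vector<std::string> out_amir, out_asite, out_states;

  if (m == 0 || L < m - (gaps ? 1 : 0)) {
    return DataFrame::create(_["start"] = out_start, _["end"] = out_end,
                             _["expectation"] = out_exp, _["gaps"] = out_gaps,
                             _["aln_mirna"] = out_amir,
                             _["aln_site"] = out_asite,
                             _["states"] = out_states,
                             _["stringsAsFactors"] = false);
  }

  // D[i][g+1]: best penalty after aligning miRNA bases 1..i having consumed
  // i+g site bases downward from anchor t; g in {-1,0,+1}, one gap total.
  std::vector<std::array<double, 3> > D(m + 1);
  std::vector<std::array<signed char, 3> > ch(m + 1);

  for (int t = m - 2; t < L; ++t) {  // anchor: site base paired to miRNA pos 1
    for (int i = 0; i <= m; ++i)
      for (int g = 0; g < 3; ++g) { D[i][g] = INF; ch[i][g] = -1; }
    D[0][1] = 0.0;
    for (int i = 1; i <= m; ++i) {
      double mult = (i >= seed_start && i <= seed_end) ? seed_mult : 1.0;
      for (int gi = 0; gi < 3; ++gi) {           // pair transition, g fixed
        int g = gi - 1;
        if (D[i - 1][gi] >= INF) continue;
        int j = t - i - g + 1;                   // site base for miRNA i
        if (j < 0 || j > t) continue;
        double pen = pair_pen[pair_state(mirna[i - 1], transcript[j])] * mult;
        if (D[i - 1][gi] + pen < D[i][gi]) {
          D[i][gi] = D[i - 1][gi] + pen;
          ch[i][gi] = 0;
        }
      }
      if (gaps && i >= 2) {
        // gap in site: miRNA base i bulged, no site base consumed
        if (D[i - 1][1] < INF) {
          double pen = p_gap * mult;
          if (D[i - 1][1] + pen < D[i][0]) {
            D[i][0] = D[i - 1][1] + pen;
            ch[i][0] = 1;
          }
        }
        // gap in miRNA: an extra site base consumed, then miRNA i pairs
        if (D[i - 1][1] < INF) {
          int j1 = t - i + 1;                    // unopposed site base
          int j2 = t - i;                        // base paired to miRNA i
          if (j2 >= 0) {
            double pen = p_gap * mult +
              pair_pen[pair_state(mirna[i - 1], transcript[j2])] * mult;
            (void)j1;
            if (D[i - 1][1] + pen < D[i][2]) {
              D[i][2] = D[i - 1][1] + pen;
              ch[i][2] = 2;
            }
          }
        }
      }
    }
    for (int gi = 0; gi < 3; ++gi) {
      int g = gi - 1;
      if (!gaps && g != 0) continue;
      double e = D[m][gi];
      if (e >= INF || e > max_expectation) continue;
      int start = t - (m + g) + 1;
      if (start < 0) continue;
      // traceback
      std::string amir, asite, states;
      int i = m, gcur = gi, consumed = m + g;
      while (i > 0) {
        signed char c = ch[i][gcur];
        int j = t - consumed + 1;                // most recently consumed base
        if (c == 0) {
          int st = pair_state(mirna[i - 1], transcript[j]);
          amir += mirna[i - 1];
          asite += transcript[j];
          states += (st == 0 ? '|' : (st == 1 ? 'o' : 'x'));
          consumed -= 1;
          i -= 1;
        } else if (c == 1) {                     // miRNA base bulged
          amir += mirna[i - 1];
          asite += '-';
          states += '-';
          i -= 1;
          gcur = 1;
        } else {                                 // extra site base
          int st = pair_state(mirna[i - 1], transcript[j]);
          amir += mirna[i - 1];
          asite += transcript[j];
          states += (st == 0 ? '|' : (st == 1 ? 'o' : 'x'));
          amir += '-';
          asite += transcript[j + 1];
          states += '-';
          consumed -= 2;
          i -= 1;
          gcur = 1;
        }
      }
      std::reverse(amir.begin(), amir.end());
      std::reverse(asite.begin(), asite.end());
      std::reverse(states.begin(), states.end());
      out_start.push_back(start);
      out_end.push_back(t + 1);
      out_exp.push_back(e);
      out_gaps.push_back(g == 0 ? 0 : 1);
      out_amir.push_back(amir);
      out_asite.push_back(asite);
      out_states.push_back(states);
    }
  }
  return DataFrame::create(_["start"] = out_start, _["end"] = out_end,
                           _["expectation"] = out_exp, _["gaps"] = out_gaps,
                           _["aln_mirna"] = out_amir, _["aln_site"] = out_asite,
                           _["states"] = out_states,
                           _["stringsAsFactors"] = false);
}
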