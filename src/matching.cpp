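// Maximum-weight matching on a general weighted graph.
//
// Implements the primal-dual blossom method (Galil, ACM Comput. Surv. 1986)
// in O(V^3): alternating-tree growth with S/T labels, blossom shrinking and
// expansion, and the four classical dual-adjustment cases. Used by the
// constrained structure decoder, where vertices are sequence positions and
// edge weights are masked, symmetrized pairing scores minus the sparsity
// penalty. Matching is maximum-weight (not maximum-cardinality): vertices
// stay unmatched when no positive-gain augmentation exists.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

class Blossom {
public:
  int nv, ne;
  std::vector<int> endpt;                 // endpt[2k], endpt[2k+1]: edge k
  std::vector<double> wt;                 // edge weights
  std::vector<std::vector<int> > nbend;   // per-vertex remote endpoint ids
  std::vector<int> mate;                  // remote endpoint or -1
  std::vector<int> label;                 // 0 free, 1 S, 2 T (+4 marker)
  std::vector<int> labelend;
  std::vector<int> inblossom;
  std::vector<int> blossomparent, blossombase;
  std::vector<std::vector<int> > blossomchilds, blossomendps;
  std::vector<int> bestedge;
  std::vector<std::vector<int> > blossombestedges;
  std::vector<int> unusedblossoms;
  std::vector<double> dualvar;
  std::vector<bool> allowedge;
  std::vector<int> queue;

  Blossom(const IntegerVector &ei, const IntegerVector &ej,
          const NumericVector &w, int n)
      : nv(n), ne(ei.size()) {
    endpt.resize(2 * ne);
    wt.resize(ne);
    nbend.assign(nv, std::vector<int>());
    for (int k = 0; k < ne; ++k) {
      endpt[2 * k] = ei[k];
      endpt[2 * k + 1] = ej[k];
      wt[k] = w[k];
      nbend[ei[k]].push_back(2 * k + 1);
      nbend[ej[k]].push_back(2 * k);
    }
    double maxw = 0.0;
    for (int k = 0; k < ne; ++k) maxw = std::max(maxw, wt[k]);
    mate.assign(nv, -1);
    label.assign(2 * nv, 0);
    labelend.assign(2 * nv, -1);
    inblossom.resize(nv);
    for (int v = 0; v < nv; ++v) inblossom[v] = v;
    blossomparent.assign(2 * nv, -1);
    blossombase.assign(2 * nv, -1);
    for (int v = 0; v < nv; ++v) blossombase[v] = v;
    blossomchilds.assign(2 * nv, std::vector<int>());
    blossomendps.assign(2 * nv, std::vector<int>());
    bestedge.assign(2 * nv, -1);
    blossombestedges.assign(2 * nv, std::vector<int>());
    for (int b = nv; b < 2 * nv; ++b) unusedblossoms.push_back(b);
    dualvar.assign(2 * nv, 0.0);
    for (int v = 0; v < nv; ++v) dualvar[v] = maxw;
    allowedge.assign(ne, false);
  }

  double slack(int k) const {
    return dualvar[endpt[2 * k]] + dualvar[endpt[2 * k + 1]] - 2.0 * wt[k];
  }

  void blossomLeaves(int b, std::vector<int> &out) const {
    if (b < nv) {
      out.push_back(b);
    } else {
      for (size_t i = 0; i < blossomchilds[b].size(); ++i)
        blossomLeaves(blossomchilds[b][i], out);
    }
  }

  void assignLabel(int w, int t, int p) {
    int b = inblossom[w];
    label[w] = label[b] = t;
    labelend[w] = labelend[b] = p;
    bestedge[w] = bestedge[b] = -1;
    if (t == 1) {
      std::vector<int> leaves;
      blossomLeaves(b, leaves);
      for (size_t i = 0; i < leaves.size(); ++i) queue.push_back(leaves[i]);
    } else if (t == 2) {
      int base = blossombase[b];
      assignLabel(endpt[mate[base]], 1, mate[base] ^ 1);
    }
  }

  int scanBlossom(int v, int w) {
    std::vector<int> path;
    int base = -1;
    while (v != -1 || w != -1) {
      int b = inblossom[v];
      if (label[b] & 4) {
        base = blossombase[b];
        break;
      }
      path.push_back(b);
      label[b] |= 4;
      if (labelend[b] == -1) {
        v = -1;
      } else {
        v = endpt[labelend[b]];
        b = inblossom[v];
        v = endpt[labelend[b]];
      }
      if (w != -1) std::swap(v, w);
    }
    for (size_t i = 0; i < path.size(); ++i) label[path[i]] &= ~4;
    return base;
  }

  void addBlossom(int base, int k) {
    int v = endpt[2 * k], w = endpt[2 * k + 1];
    int bb = inblossom[base], bv = inblossom[v], bw = inblossom[w];
    int b = unusedblossoms.back();
    unusedblossoms.pop_back();
    blossombase[b] = base;
    blossomparent[b] = -1;
    blossomparent[bb] = b;
    std::vector<int> path, endps;
    while (bv != bb) {
      blossomparent[bv] = b;
      path.push_back(bv);
      endps.push_back(labelend[bv]);
      v = endpt[labelend[bv]];
      bv = inblossom[v];
    }
    path.push_back(bb);
    std::reverse(path.begin(), path.end());
    std::reverse(endps.begin(), endps.end());
    endps.push_back(2 * k);
    while (bw != bb) {
      blossomparent[bw] = b;
      path.push_back(bw);
      endps.push_back(labelend[bw] ^ 1);
      w = endpt[labelend[bw]];
      bw = inblossom[w];
    }
    blossomchilds[b] = path;
    blossomendps[b] = endps;
    label[b] = 1;
    labelend[b] = labelend[bb];
    dualvar[b] = 0.0;
    std::vector<int> leaves;
    blossomLeaves(b, leaves);
    for (size_t i = 0; i < leaves.size(); ++i) {
      if (label[inblossom[leaves[i]]] == 2) queue.push_back(leaves[i]);
      inblossom[leaves[i]] = b;
    }
    // merge least-slack edges to other S-blossoms
    std::vector<int> bestedgeto(2 * nv, -1);
    for (size_t pi = 0; pi < path.size(); ++pi) {
      int bvv = path[pi];
      std::vector<int> nblist;
      if (!blossombestedges[bvv].empty()) {
        nblist = blossombestedges[bvv];
      } else {
        std::vector<int> lv;
        blossomLeaves(bvv, lv);
        for (size_t i = 0; i < lv.size(); ++i)
          for (size_t j = 0; j < nbend[lv[i]].size(); ++j)
            nblist.push_back(nbend[lv[i]][j] / 2);
      }
      for (size_t i = 0; i < nblist.size(); ++i) {
        int kk = nblist[i];
        int jj = endpt[2 * kk + 1];
        if (inblossom[jj] == b) jj = endpt[2 * kk];
        int bj = inblossom[jj];
        if (bj != b && label[bj] == 1 &&
            (bestedgeto[bj] == -1 || slack(kk) < slack(bestedgeto[bj])))
          bestedgeto[bj] = kk;
      }
      blossombestedges[bvv].clear();
      bestedge[bvv] = -1;
    }
    blossombestedges[b].clear();
    for (int bj = 0; bj < 2 * nv; ++bj)
      if (bestedgeto[bj] != -1) blossombestedges[b].push_back(bestedgeto[bj]);
    bestedge[b] = -1;
    for (size_t i = 0; i < blossombestedges[b].size(); ++i) {
      int kk = blossombestedges[b][i];
      if (bestedge[b] == -1 || slack(kk) < slack(bestedge[b])) bestedge[b] = kk;
    }
  }

  void expandBlossom(int b, bool endstage) {
    for (size_t si = 0; si < blossomchilds[b].size(); ++si) {
      int s = blossomchilds[b][si];
      blossomparent[s] = -1;
      if (s < nv) {
        inblossom[s] = s;
      } else if (endstage && dualvar[s] == 0.0) {
        expandBlossom(s, endstage);
      } else {
        std::vector<int> lv;
        blossomLeaves(s, lv);
        for (size_t i = 0; i < lv.size(); ++i) inblossom[lv[i]] = s;
      }
    }
    if (!endstage && label[b] == 2) {
      int entrychild = inblossom[endpt[labelend[b] ^ 1]];
      int j = -1;
      for (size_t i = 0; i < blossomchilds[b].size(); ++i)
        if (blossomchilds[b][i] == entrychild) { j = (int)i; break; }
      int jstep, endptrick;
      int nch = (int)blossomchilds[b].size();
      if (j & 1) {
        j -= nch;
        jstep = 1;
        endptrick = 0;
      } else {
        jstep = -1;
        endptrick = 1;
      }
      int p = labelend[b];
      while (j != 0) {
        label[endpt[p ^ 1]] = 0;
        int idx = ((j - endptrick) % nch + nch) % nch;
        label[endpt[blossomendps[b][idx] ^ endptrick ^ 1]] = 0;
        assignLabel(endpt[p ^ 1], 2, p);
        allowedge[blossomendps[b][idx] / 2] = true;
        j += jstep;
        idx = ((j - endptrick) % nch + nch) % nch;
        p = blossomendps[b][idx] ^ endptrick;
        allowedge[p / 2] = true;
        j += jstep;
      }
      int bv = blossomchilds[b][0];
      label[endpt[p ^ 1]] = label[bv] = 2;
      labelend[endpt[p ^ 1]] = labelend[bv] = p;
      bestedge[bv] = -1;
      j += jstep;
      while (blossomchilds[b][((j % nch) + nch) % nch] != entrychild) {
        bv = blossomchilds[b][((j % nch) + nch) % nch];
        if (label[bv] == 1) {
          j += jstep;
          continue;
        }
        std::vector<int> lv;
        blossomLeaves(bv, lv);
        int vlab = -1;
        for (size_t i = 0; i < lv.size(); ++i)
          if (label[lv[i]] != 0) { vlab = lv[i]; break; }
        if (vlab != -1) {
          label[vlab] = 0;
          label[endpt[mate[blossombase[bv]]]] = 0;
          assignLabel(vlab, 2, labelend[vlab]);
        }
        j += jstep;
      }
    }
    label[b] = labelend[b] = -1;
    blossomchilds[b].clear();
    blossomendps[b].clear();
    blossombase[b] = -1;
    blossombestedges[b].clear();
    bestedge[b] = -1;
    unusedblossoms.push_back(b);
  }

  void augmentBlossom(int b, int v) {
    int t = v;
    while (blossomparent[t] != b) t = blossomparent[t];
    if (t >= nv) augmentBlossom(t, v);
    int i = -1;
    int nch = (int)blossomchilds[b].size();
    for (int q = 0; q < nch; ++q)
      if (blossomchilds[b][q] == t) { i = q; break; }
    int j = i, jstep, endptrick;
    if (i & 1) {
      j -= nch;
      jstep = 1;
      endptrick = 0;
    } else {
      jstep = -1;
      endptrick = 1;
    }
    while (j != 0) {
      j += jstep;
      int idx = ((j % nch) + nch) % nch;
      t = blossomchilds[b][idx];
      int pidx = (((j - endptrick) % nch) + nch) % nch;
      int p = blossomendps[b][pidx] ^ endptrick;
      if (t >= nv) augmentBlossom(t, endpt[p]);
      j += jstep;
      idx = ((j % nch) + nch) % nch;
      t = blossomchilds[b][idx];
      if (t >= nv) augmentBlossom(t, endpt[p ^ 1]);
      mate[endpt[p]] = p ^ 1;
      mate[endpt[p ^ 1]] = p;
    }
    std::vector<int> nc(blossomchilds[b].begin() + i, blossomchilds[b].end());
    nc.insert(nc.end(), blossomchilds[b].begin(), blossomchilds[b].begin() + i);
    std::vector<int> np(blossomendps[b].begin() + i, blossomendps[b].end());
    np.insert(np.end(), blossomendps[b].begin(), blossomendps[b].begin() + i);
    blossomchilds[b] = nc;
    blossomendps[b] = np;
    blossombase[b] = blossombase[blossomchilds[b][0]];
  }

  void augmentMatching(int k) {
    int v = endpt[2 * k], w = endpt[2 * k + 1];
    for (int side = 0; side < 2; ++side) {
      int s = side == 0 ? v : w;
      int p = side == 0 ? 2 * k + 1 : 2 * k;
      for (;;) {
        int bs = inblossom[s];
        if (bs >= nv) augmentBlossom(bs, s);
        mate[s] = p;
        if (labelend[bs] == -1) break;
        int t = endpt[labelend[bs]];
        int bt = inblossom[t];
        s = endpt[labelend[bt]];
        int j = endpt[labelend[bt] ^ 1];
        if (bt >= nv) augmentBlossom(bt, j);
        mate[j] = labelend[bt];
        p = labelend[bt] ^ 1;
      }
    }
  }

  IntegerVector run() {
    if (ne == 0) {
      IntegerVector out(nv, -1);
      return out;
    }
    for (int stage = 0; stage < nv; ++stage) {
      std::fill(label.begin(), label.end(), 0);
      std::fill(bestedge.begin(), bestedge.end(), -1);
      for (int b = nv; b < 2 * nv; ++b) blossombestedges[b].clear();
      std::fill(allowedge.begin(), allowedge.end(), false);
      queue.clear();
      for (int v = 0; v < nv; ++v)
        if (mate[v] == -1 && label[inblossom[v]] == 0) assignLabel(v, 1, -1);
      bool augmented = false;
      for (;;) {
        while (!queue.empty() && !augmented) {
          int v = queue.back();
          queue.pop_back();
          for (size_t pi = 0; pi < nbend[v].size(); ++pi) {
            int p = nbend[v][pi];
            int k = p / 2;
            int w = endpt[p];
            if (inblossom[v] == inblossom[w]) continue;
            double kslack = 0.0;
            if (!allowedge[k]) {
              kslack = slack(k);
              if (kslack <= 1e-12) allowedge[k] = true;
            }
            if (allowedge[k]) {
              if (label[inblossom[w]] == 0) {
                assignLabel(w, 2, p ^ 1);
              } else if (label[inblossom[w]] == 1) {
                int base = scanBlossom(v, w);
                if (base >= 0) {
                  addBlossom(base, k);
                } else {
                  augmentMatching(k);
                  augmented = true;
                  break;
                }
              } else if (label[w] == 0) {
                label[w] = 2;
                labelend[w] = p ^ 1;
              }
            } else if (label[inblossom[w]] == 1) {
              int b = inblossom[v];
              if (bestedge[b] == -1 || kslack < slack(bestedge[b]))
                bestedge[b] = k;
            } else if (label[w] == 0) {
              if (bestedge[w] == -1 || kslack < slack(bestedge[w]))
                bestedge[w] = k;
            }
          }
          if (augmented) break;
        }
        if (augmented) break;
        // dual adjustment
        int deltatype = 1;
        double delta = dualvar[0];
        for (int v = 1; v < nv; ++v) delta = std::min(delta, dualvar[v]);
        int deltaedge = -1, deltablossom = -1;
        for (int v = 0; v < nv; ++v) {
          if (label[inblossom[v]] == 0 && bestedge[v] != -1) {
            double d = slack(bestedge[v]);
            if (d < delta) {
              delta = d;
              deltatype = 2;
              deltaedge = bestedge[v];
            }
          }
        }
        for (int b = 0; b < 2 * nv; ++b) {
          if (blossomparent[b] == -1 && label[b] == 1 && bestedge[b] != -1) {
            double d = slack(bestedge[b]) / 2.0;
            if (d < delta) {
              delta = d;
              deltatype = 3;
              deltaedge = bestedge[b];
            }
          }
        }
        for (int b = nv; b < 2 * nv; ++b) {
          if (blossombase[b] >= 0 && blossomparent[b] == -1 && label[b] == 2) {
            if (dualvar[b] < delta) {
              delta = dualvar[b];
              deltatype = 4;
              deltablossom = b;
            }
          }
        }
        for (int v = 0; v < nv; ++v) {
          if (label[inblossom[v]] == 1) dualvar[v] -= delta;
          else if (label[inblossom[v]] == 2) dualvar[v] += delta;
        }
        for (int b = nv; b < 2 * nv; ++b) {
          if (blossombase[b] >= 0 && blossomparent[b] == -1) {
            if (label[b] == 1) dualvar[b] += delta;
            else if (label[b] == 2) dualvar[b] -= delta;
          }
        }
        if (deltatype == 1) break; // no further improvement possible
        if (deltatype == 2) {
          allowedge[deltaedge] = true;
          int i = endpt[2 * deltaedge];
          if (label[inblossom[i]] == 0) i = endpt[2 * deltaedge + 1];
          queue.push_back(i);
        } else if (deltatype == 3) {
          allowedge[deltaedge] = true;
          queue.push_back(endpt[2 * deltaedge]);
        } else {
          expandBlossom(deltablossom, false);
        }
      }
      if (!augmented) break;
      for (int b = nv; b < 2 * nv; ++b) {
        if (blossomparent[b] == -1 && blossombase[b] >= 0 && label[b] == 1 &&
            dualvar[b] == 0.0)
          expandBlossom(b, true);
      }
    }
    IntegerVector out(nv);
    for (int v = 0; v < nv; ++v)
      out[v] = mate[v] == -1 ? -1 : endpt[mate[v]];
    return out;
  }
};

} // namespace

//' @title Exact maximum-weight matching (internal)
//' @description Blossom-method maximum-weight matching on a general graph.
//' @param ei,ej Integer vectors of 0-based edge endpoints.
//' @param w Numeric edge weights (assumed positive).
//' @param n Number of vertices.
//' @return Integer vector of length `n`: 0-based matched partner or -1.
//' @keywords internal
// [[Rcpp::export]]
IntegerVector max_weight_matching_cpp(IntegerVector ei, IntegerVector ej,
                                      NumericVector w, int n) {
  if (ei.size() != ej.size() || ei.size() != w.size())
    stop("edge vectors must have equal length");
  for (int k = 0; k < ei.size(); ++k) {
    if (ei[k] < 0 || ei[k] >= n || ej[k] < 0 || ej[k] >= n || ei[k] == ej[k])
      stop("invalid edge endpoint");
  }
  Blossom B(ei, ej, w, n);
  return B.run();
}
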