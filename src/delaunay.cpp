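// Incremental (Bowyer-Watson) 3D Delaunay triangulation.
//
// The alpha-shape machinery needs a tetrahedralization of cluster point
// sets; no suitable triangulation backend is available to link against, so
// this file implements one. Robustness strategy: coordinates are normalized
// to unit scale and symbolically jittered by ~1e-9 with a deterministic
// xorshift stream, which removes the exact degeneracies (cospherical,
// coplanar) that double-precision predicates cannot order. The jitter is
// only used for the combinatorial structure; all metric quantities are
// computed afterwards from the original coordinates.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <utility>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Tet {
  int v[4];    // vertex ids
  int adj[4];  // adj[i] = tet sharing the face opposite v[i], or -1
  bool alive;
};

// face opposite local vertex i, ordered so that orient3d(face, v[i]) > 0
// for a positively oriented tet
const int FACE[4][3] = {{1, 3, 2}, {0, 2, 3}, {0, 3, 1}, {0, 1, 2}};

inline double orient3d(const double* a, const double* b, const double* c,
                       const double* d) {
  double adx = a[0] - d[0], ady = a[1] - d[1], adz = a[2] - d[2];
  double bdx = b[0] - d[0], bdy = b[1] - d[1], bdz = b[2] - d[2];
  double cdx = c[0] - d[0], cdy = c[1] - d[1], cdz = c[2] - d[2];
  return adx * (bdy * cdz - bdz * cdy) - ady * (bdx * cdz - bdz * cdx) +
         adz * (bdx * cdy - bdy * cdx);
}

// > 0 iff e lies inside the circumsphere of positively oriented (a,b,c,d)
inline double insphere(const double* a, const double* b, const double* c,
                       const double* d, const double* e) {
  double aex = a[0] - e[0], aey = a[1] - e[1], aez = a[2] - e[2];
  double bex = b[0] - e[0], bey = b[1] - e[1], bez = b[2] - e[2];
  double cex = c[0] - e[0], cey = c[1] - e[1], cez = c[2] - e[2];
  double dex = d[0] - e[0], dey = d[1] - e[1], dez = d[2] - e[2];

  double ab = aex * bey - bex * aey, ac = aex * cey - cex * aey;
  double ad = aex * dey - dex * aey, bc = bex * cey - cex * bey;
  double bd = bex * dey - dex * bey, cd = cex * dey - dex * cey;

  double abc = aez * bc - bez * ac + cez * ab;
  double abd = aez * bd - bez * ad + dez * ab;
  double acd = aez * cd - cez * ad + dez * ac;
  double bcd = bez * cd - cez * bd + dez * bc;

  double alift = aex * aex + aey * aey + aez * aez;
  double blift = bex * bex + bey * bey + bez * bez;
  double clift = cex * cex + cey * cey + cez * cez;
  double dlift = dex * dex + dey * dey + dez * dez;

  return dlift * abc - clift * abd + blift * acd - alift * bcd;
}

struct Xorshift {
  uint64_t s;
  explicit Xorshift(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  double unif() {  // in (-0.5, 0.5)
    return (double)(next() >> 11) / 9007199254740992.0 - 0.5;
  }
};

class Delaunay3 {
 public:
  std::vector<double> pts;  // (n + 4) * 3, normalized + jittered
  int n;
  std::vector<Tet> tets;
  int last_tet;

  const double* P(int i) const { return &pts[3 * i]; }

  explicit Delaunay3(const NumericMatrix& x, double jitter) {
    n = x.nrow();
    pts.resize(3 * (n + 4));
    double lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = R_PosInf;
      hi[d] = R_NegInf;
    }
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double v = x(i, d);
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    double ext = 0.0;
    for (int d = 0; d < 3; ++d) ext = std::max(ext, hi[d] - lo[d]);
    if (ext <= 0.0) ext = 1.0;
    Xorshift rng(0x2545F4914F6CDD1DULL);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        pts[3 * i + d] =
            (x(i, d) - 0.5 * (lo[d] + hi[d])) / ext + jitter * rng.unif();
    // enclosing super tetrahedron (points live in [-0.5-j, 0.5+j]^3)
    const double B = 2000.0;
    double sv[4][3] = {{0, 0, 3 * B}, {-2 * B, -2 * B, -B},
                       {2 * B, -2 * B, -B}, {0, 2 * B, -B}};
    for (int k = 0; k < 4; ++k)
      for (int d = 0; d < 3; ++d) pts[3 * (n + k) + d] = sv[k][d];

    Tet t0;
    t0.v[0] = n;
    t0.v[1] = n + 1;
    t0.v[2] = n + 2;
    t0.v[3] = n + 3;
    if (orient3d(P(t0.v[0]), P(t0.v[1]), P(t0.v[2]), P(t0.v[3])) < 0)
      std::swap(t0.v[2], t0.v[3]);
    t0.adj[0] = t0.adj[1] = t0.adj[2] = t0.adj[3] = -1;
    t0.alive = true;
    tets.push_back(t0);
    last_tet = 0;
  }

  // walk to a tetrahedron containing p; returns tet id or -1
  int locate(const double* p) const {
    int cur = last_tet;
    if (cur < 0 || cur >= (int)tets.size() || !tets[cur].alive) {
      cur = -1;
      for (int i = (int)tets.size() - 1; i >= 0; --i)
        if (tets[i].alive) {
          cur = i;
          break;
        }
      if (cur < 0) return -1;
    }
    size_t guard = 8 * tets.size() + 64;
    while (guard--) {
      const Tet& t = tets[cur];
      int worst = -1;
      double worst_val = -1e-13;
      for (int i = 0; i < 4; ++i) {
        double o = orient3d(P(t.v[FACE[i][0]]), P(t.v[FACE[i][1]]),
                            P(t.v[FACE[i][2]]), p);
        if (o < worst_val) {
          worst_val = o;
          worst = i;
        }
      }
      if (worst < 0) return cur;  // inside (or on boundary) of cur
      int nxt = t.adj[worst];
      if (nxt < 0 || !tets[nxt].alive) return cur;  // shouldn't happen
      cur = nxt;
    }
    // fallback: exhaustive scan
    int best = -1;
    double best_min = R_NegInf;
    for (int id = 0; id < (int)tets.size(); ++id) {
      if (!tets[id].alive) continue;
      const Tet& t = tets[id];
      double mn = R_PosInf;
      for (int i = 0; i < 4; ++i) {
        double o = orient3d(P(t.v[FACE[i][0]]), P(t.v[FACE[i][1]]),
                            P(t.v[FACE[i][2]]), p);
        if (o < mn) mn = o;
      }
      if (mn > best_min) {
        best_min = mn;
        best = id;
      }
    }
    return best;
  }

  void insert(int ip) {
    const double* p = P(ip);
    int t0 = locate(p);
    if (t0 < 0) stop("triangulation internal error: point location failed");

    // carve cavity of tets whose circumsphere contains p
    std::vector<int> bad;
    std::vector<char> inbad(tets.size(), 0);
    std::vector<int> stack;
    stack.push_back(t0);
    inbad[t0] = 1;
    while (!stack.empty()) {
      int id = stack.back();
      stack.pop_back();
      bad.push_back(id);
      const Tet t = tets[id];
      for (int i = 0; i < 4; ++i) {
        int nb = t.adj[i];
        if (nb < 0 || inbad[nb] || !tets[nb].alive) continue;
        const Tet& u = tets[nb];
        if (insphere(P(u.v[0]), P(u.v[1]), P(u.v[2]), P(u.v[3]), p) > 0) {
          inbad[nb] = 1;
          stack.push_back(nb);
        }
      }
    }

    // boundary faces of the cavity -> new tets joining p
    struct BFace {
      int a, b, c;   // ordered so orient3d(a,b,c, interior) > 0
      int outside;   // neighboring tet beyond the face (-1 on hull)
    };
    std::vector<BFace> faces;
    for (int id : bad) {
      const Tet& t = tets[id];
      for (int i = 0; i < 4; ++i) {
        int nb = t.adj[i];
        if (nb >= 0 && inbad[nb]) continue;
        BFace f;
        f.a = t.v[FACE[i][0]];
        f.b = t.v[FACE[i][1]];
        f.c = t.v[FACE[i][2]];
        f.outside = nb;
        faces.push_back(f);
      }
    }
    for (int id : bad) tets[id].alive = false;

    std::vector<int> created(faces.size());
    for (size_t k = 0; k < faces.size(); ++k) {
      Tet nt;
      nt.v[0] = faces[k].a;
      nt.v[1] = faces[k].b;
      nt.v[2] = faces[k].c;
      nt.v[3] = ip;
      nt.adj[0] = nt.adj[1] = nt.adj[2] = nt.adj[3] = -1;
      nt.adj[3] = faces[k].outside;
      nt.alive = true;
      created[k] = (int)tets.size();
      tets.push_back(nt);
      // hook the outside tet back to us
      int out = faces[k].outside;
      if (out >= 0) {
        Tet& u = tets[out];
        for (int i = 0; i < 4; ++i) {
          int fa = u.v[FACE[i][0]], fb = u.v[FACE[i][1]], fc = u.v[FACE[i][2]];
          int s1 = fa + fb + fc, s2 = faces[k].a + faces[k].b + faces[k].c;
          if (s1 == s2) {
            int mx1 = std::max(fa, std::max(fb, fc));
            int mx2 = std::max(faces[k].a, std::max(faces[k].b, faces[k].c));
            int mn1 = std::min(fa, std::min(fb, fc));
            int mn2 = std::min(faces[k].a, std::min(faces[k].b, faces[k].c));
            if (mx1 == mx2 && mn1 == mn2) {
              u.adj[i] = created[k];
              break;
            }
          }
        }
      }
    }
    // stitch the new tets to each other across the faces (p, edge)
    std::map<std::pair<int, int>, std::pair<int, int>> edge_owner;
    for (size_t k = 0; k < faces.size(); ++k) {
      int vv[3] = {faces[k].a, faces[k].b, faces[k].c};
      for (int e = 0; e < 3; ++e) {
        // face of new tet opposite local vertex e is (other two, p)
        int u1 = vv[(e + 1) % 3], u2 = vv[(e + 2) % 3];
        std::pair<int, int> key(std::min(u1, u2), std::max(u1, u2));
        auto it = edge_owner.find(key);
        if (it == edge_owner.end()) {
          edge_owner[key] = std::make_pair(created[k], e);
        } else {
          tets[created[k]].adj[e] = it->second.first;
          tets[it->second.first].adj[it->second.second] = created[k];
        }
      }
    }
    last_tet = created.empty() ? last_tet : created[0];
  }
};

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".delaunay3d_cpp")]]
IntegerMatrix delaunay3d_cpp(NumericMatrix x, double jitter = 1e-9) {
  int n = x.nrow();
  if (n < 4) stop("need at least 4 points");
  Delaunay3 dt(x, jitter);
  // insert in a deterministic shuffled order (helps conditioning)
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  Xorshift rng(0x853c49e6748fea9bULL);
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(rng.next() % (uint64_t)(i + 1));
    std::swap(order[i], order[j]);
  }
  for (int i = 0; i < n; ++i) dt.insert(order[i]);

  int m = 0;
  for (const Tet& t : dt.tets)
    if (t.alive && t.v[0] < n && t.v[1] < n && t.v[2] < n && t.v[3] < n) ++m;
  IntegerMatrix out(m, 4);
  int r = 0;
  for (const Tet& t : dt.tets) {
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
    for (int d = 0; d < 4; ++d) out(r, d) = t.v[d] + 1;
    ++r;
  }
  return out;
}
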