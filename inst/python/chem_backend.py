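"""RDKit backend for the regiopd R package.

Reads one JSON request from stdin ({"op": ..., ...}) and writes one JSON
response to stdout ({"ok": true, ...} or {"ok": false, "error": ...}).
All randomized operations take explicit seeds; given identical requests the
responses are bit-identical.

Conventions: atom indices are 0-based and refer to the input SMILES atom
order as parsed by RDKit (no canonical renumbering).
"""

import json
import random
import sys

from rdkit import Chem, DistanceGeometry, RDLogger
from rdkit.Chem import AllChem, rdDistGeom, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")

# Pyykko & Atsumi single-bond covalent radii (Angstrom) for the elements the
# workflow encounters; fallback 0.75 for anything exotic.
COVALENT_RADII = {
    1: 0.32, 5: 0.85, 6: 0.75, 7: 0.71, 8: 0.63, 9: 0.64, 14: 1.16,
    15: 1.11, 16: 1.03, 17: 0.99, 35: 1.14, 46: 1.20, 53: 1.33,
}

LONE_PAIR_VE = {7: 5, 8: 6, 15: 5, 16: 6}


def fail(msg):
    json.dump({"ok": False, "error": str(msg)}, sys.stdout)
    sys.stdout.write("\n")
    sys.exit(0)


def get_mol(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        fail("unparsable SMILES: " + str(smiles))
    return mol


def has_lone_pair(atom):
    z = atom.GetAtomicNum()
    if z not in LONE_PAIR_VE:
        return False
    ve = LONE_PAIR_VE[z]
    lp = (ve - atom.GetFormalCharge() - atom.GetTotalValence()) / 2.0
    if lp < 1:
        return False
    # pyrrole-type aromatic N/P: the lone pair is part of the aromatic sextet
    if atom.GetIsAromatic() and z in (7, 15):
        if atom.GetDegree() + atom.GetTotalNumHs() >= 3:
            return False
    return True


def is_sp2_ch(atom):
    return (atom.GetAtomicNum() == 6
            and atom.GetHybridization() == Chem.HybridizationType.SP2
            and atom.GetTotalNumHs() >= 1)


def op_parse(req):
    mol = get_mol(req["smiles"])
    donors = set(req.get("donor_elements", ["N", "O", "S"]))
    atoms = []
    for a in mol.GetAtoms():
        atoms.append({
            "atom": a.GetIdx(),
            "element": a.GetSymbol(),
            "z": a.GetAtomicNum(),
            "aromatic": a.GetIsAromatic(),
            "hybridization": str(a.GetHybridization()),
            "charge": a.GetFormalCharge(),
            "n_h": a.GetTotalNumHs(),
            "in_ring": a.IsInRing(),
            "sp2_ch": is_sp2_ch(a),
            "dg_donor": a.GetSymbol() in donors and has_lone_pair(a),
        })
    bonds = [{
        "i": b.GetBeginAtomIdx(), "j": b.GetEndAtomIdx(),
        "order": b.GetBondTypeAsDouble(), "aromatic": b.GetIsAromatic(),
    } for b in mol.GetBonds()]
    return {
        "canonical_smiles": Chem.MolToSmiles(mol),
        "atoms": atoms,
        "bonds": bonds,
        "net_charge": Chem.GetFormalCharge(mol),
        "n_rot": rdMolDescriptors.CalcNumRotatableBonds(mol),
    }


def marked_site_smiles(mol, idx, isotope=99):
    """Canonical SMILES with one explicit isotope-labelled H at atom idx."""
    rw = Chem.RWMol(mol)
    a = rw.GetAtomWithIdx(idx)
    if a.GetTotalNumHs() < 1:
        fail("atom %d has no hydrogen to mark" % idx)
    h = Chem.Atom(1)
    h.SetIsotope(isotope)
    hi = rw.AddAtom(h)
    rw.AddBond(idx, hi, Chem.BondType.SINGLE)
    a = rw.GetAtomWithIdx(idx)
    a.SetNumExplicitHs(a.GetTotalNumHs() - 1)
    a.SetNoImplicit(True)
    m = rw.GetMol()
    Chem.SanitizeMol(m)
    return Chem.MolToSmiles(m)


def marked_dg_smiles(mol, idx):
    """Canonical SMILES with a dummy atom coordinated to atom idx."""
    rw = Chem.RWMol(mol)
    di = rw.AddAtom(Chem.Atom(0))
    rw.AddBond(idx, di, Chem.BondType.DATIVE)
    m = rw.GetMol()
    Chem.SanitizeMol(m)
    return Chem.MolToSmiles(m)


def op_site_marks(req):
    mol = get_mol(req["smiles"])
    return {"marks": [marked_site_smiles(mol, int(i)) for i in req["sites"]]}


def op_dg_marks(req):
    mol = get_mol(req["smiles"])
    return {"marks": [marked_dg_smiles(mol, int(i)) for i in req["atoms"]]}


def op_renumber(req):
    mol = get_mol(req["smiles"])
    rng = random.Random(int(req["seed"]))
    out = []
    n = mol.GetNumAtoms()
    for _ in range(int(req["n"])):
        perm = list(range(n))
        rng.shuffle(perm)
        m2 = Chem.RenumberAtoms(mol, perm)
        out.append({"smiles": Chem.MolToSmiles(m2, canonical=False),
                    "perm": perm})
    return {"renumbered": out}


def op_smarts(req):
    mol = get_mol(req["smiles"])
    res = []
    for k, sm in enumerate(req["patterns"]):
        q = Chem.MolFromSmarts(sm)
        if q is None:
            fail("unparsable SMARTS: " + sm)
        for match in mol.GetSubstructMatches(q, uniquify=True):
            res.append({
                "pattern": k,
                "atoms": list(match),
                "z": [mol.GetAtomWithIdx(i).GetAtomicNum() for i in match],
            })
    return {"matches": res}


def _ring2d_one(mol, site, dg):
    path = Chem.GetShortestPath(mol, site, dg)
    rw = Chem.RWMol(mol)
    pd = rw.AddAtom(Chem.Atom(46))
    rw.AddBond(pd, site, Chem.BondType.SINGLE)
    rw.AddBond(dg, pd, Chem.BondType.DATIVE)
    m = rw.GetMol()
    try:
        Chem.SanitizeMol(m)
        AllChem.Compute2DCoords(m)
    except Exception as e:  # noqa: BLE001 - reported as embed failure
        return {"embed_ok": False, "reason": str(e)}
    conf = m.GetConformer()
    ring = list(path) + [pd]
    coords = [[conf.GetAtomPosition(i).x, conf.GetAtomPosition(i).y]
              for i in ring]
    return {"embed_ok": True, "ring_atoms": list(path), "coords": coords}


def op_ring2d(req):
    """2D coordinates of palladacycle rings closed through a Pd placeholder.

    Accepts one (site, dg) pair or parallel lists of pairs.
    """
    mol = get_mol(req["smiles"])
    if "pairs" in req:
        out = [_ring2d_one(mol, int(p["site"]), int(p["dg"]))
               for p in req["pairs"]]
        return {"results": out}
    return _ring2d_one(mol, int(req["site"]), int(req["dg"]))


def _remove_one_h(rw, site):
    hs = [n.GetIdx() for n in rw.GetAtomWithIdx(site).GetNeighbors()
          if n.GetAtomicNum() == 1]
    if not hs:
        fail("site atom %d has no explicit hydrogen after AddHs" % site)
    rw.RemoveAtom(hs[0])


def op_strain(req):
    """CCl2 dummy-palladacycle MMFF94s strain screen (OOP + torsion terms).

    Accepts one (site, dg) pair or a list under "pairs".
    """
    mol = get_mol(req["smiles"])
    if "pairs" in req:
        out = []
        for p in req["pairs"]:
            sub = dict(req)
            sub.pop("pairs")
            sub["site"], sub["dg"] = p["site"], p["dg"]
            out.append(_strain_one(sub, mol))
        return {"results": out}
    return _strain_one(req, mol)


def _strain_one(req, mol):
    site, dg = int(req["site"]), int(req["dg"])
    seed = int(req.get("seed", 12648430))
    attempts = int(req.get("attempts", 10))
    rw = Chem.RWMol(Chem.AddHs(mol))
    _remove_one_h(rw, site)
    c = rw.AddAtom(Chem.Atom(6))
    for _ in range(2):
        cl = rw.AddAtom(Chem.Atom(17))
        rw.AddBond(c, cl, Chem.BondType.SINGLE)
    rw.AddBond(c, site, Chem.BondType.SINGLE)
    rw.AddBond(dg, c, Chem.BondType.DATIVE)
    m = rw.GetMol()
    try:
        Chem.SanitizeMol(m)
    except Exception as e:  # noqa: BLE001
        return {"embed_ok": False, "reason": "sanitize: " + str(e)}
    cid = -1
    for k in range(attempts):
        ps = rdDistGeom.ETKDGv3()
        ps.randomSeed = seed + k
        cid = rdDistGeom.EmbedMolecule(m, ps)
        if cid >= 0:
            break
    if cid < 0:
        return {"embed_ok": False, "reason": "distance-geometry embedding failed"}
    if not AllChem.MMFFHasAllMoleculeParams(m):
        return {"embed_ok": True, "param_ok": False,
                "reason": "MMFF94s parameters missing"}
    AllChem.MMFFOptimizeMolecule(m, mmffVariant="MMFF94s", maxIters=2000)
    props = AllChem.MMFFGetMoleculeProperties(m, mmffVariant="MMFF94s")
    props.SetMMFFBondTerm(False)
    props.SetMMFFAngleTerm(False)
    props.SetMMFFStretchBendTerm(False)
    props.SetMMFFVdWTerm(False)
    props.SetMMFFEleTerm(False)
    ff = AllChem.MMFFGetMoleculeForceField(m, props)
    return {"embed_ok": True, "param_ok": True,
            "strain_kcal": ff.CalcEnergy()}


def build_pd_complex(mol, site, dg):
    """Substrate minus the site H, plus Pd and a kappa-2 acetate."""
    rw = Chem.RWMol(Chem.AddHs(mol))
    _remove_one_h(rw, site)
    pd = rw.AddAtom(Chem.Atom(46))
    cc = rw.AddAtom(Chem.Atom(6))
    o1 = rw.AddAtom(Chem.Atom(8))
    o2 = rw.AddAtom(Chem.Atom(8))
    cm = rw.AddAtom(Chem.Atom(6))
    rw.AddBond(cc, o1, Chem.BondType.DOUBLE)
    rw.AddBond(cc, o2, Chem.BondType.SINGLE)
    rw.AddBond(cc, cm, Chem.BondType.SINGLE)
    for _ in range(3):
        h = rw.AddAtom(Chem.Atom(1))
        rw.AddBond(cm, h, Chem.BondType.SINGLE)
    rw.AddBond(pd, site, Chem.BondType.SINGLE)
    rw.AddBond(dg, pd, Chem.BondType.DATIVE)
    rw.AddBond(o1, pd, Chem.BondType.DATIVE)
    rw.AddBond(o2, pd, Chem.BondType.DATIVE)
    # acetate carries the -1, Pd the +2 balanced by the aryl sigma-bond carbon:
    # formal bookkeeping keeps the complex at the substrate's net charge.
    rw.GetAtomWithIdx(o2).SetFormalCharge(-1)
    rw.GetAtomWithIdx(pd).SetFormalCharge(1)
    m = rw.GetMol()
    Chem.SanitizeMol(m)
    return m, {"pd": pd, "o1": o1, "o2": o2, "site": site, "dg": dg}


def complex_payload(m, ix):
    bonds = []
    pd = ix["pd"]
    for b in m.GetBonds():
        bonds.append({"i": b.GetBeginAtomIdx(), "j": b.GetEndAtomIdx(),
                      "order": b.GetBondTypeAsDouble(),
                      "pd_bond": pd in (b.GetBeginAtomIdx(), b.GetEndAtomIdx())})
    return {
        "symbols": [a.GetSymbol() for a in m.GetAtoms()],
        "z": [a.GetAtomicNum() for a in m.GetAtoms()],
        "bonds": bonds,
        "index_map": ix,
        "net_charge": Chem.GetFormalCharge(m),
        "n_atoms": m.GetNumAtoms(),
    }


def op_complex(req):
    mol = get_mol(req["smiles"])
    m, ix = build_pd_complex(mol, int(req["site"]), int(req["dg"]))
    out = complex_payload(m, ix)
    out["molblock"] = Chem.MolToMolBlock(m, kekulize=True)
    out["n_rot_substrate"] = rdMolDescriptors.CalcNumRotatableBonds(mol)
    return out


def _set_bound(bm, i, j, lo, hi):
    a, b = sorted((i, j))
    bm[b][a] = lo
    bm[a][b] = hi


def pd_bounds_params(m, ix, seed, cross=True):
    """ETKDG parameters encoding the square-planar Pd coordination sphere.

    Pd-ligand bounds come from covalent radii with +/-15% slack; the
    ligand-ligand cross distances (trans partners at the diagonal, cis
    partners at ~90 degrees) shape the embedding toward the square-planar
    intermediate, since distance geometry knows nothing about metals.
    """
    bm = rdDistGeom.GetMoleculeBoundsMatrix(m)
    pd = ix["pd"]
    dist = {}
    for key in ("site", "dg", "o1", "o2"):
        j = ix[key]
        zj = m.GetAtomWithIdx(j).GetAtomicNum()
        d = COVALENT_RADII[46] + COVALENT_RADII.get(zj, 0.75)
        dist[key] = d
        _set_bound(bm, pd, j, 0.85 * d, 1.15 * d)
    if cross:
        for a, b in (("site", "o1"), ("dg", "o2")):  # trans: linear through Pd
            d = dist[a] + dist[b]
            _set_bound(bm, ix[a], ix[b], 0.90 * d, 1.10 * d)
        for a, b in (("site", "o2"), ("dg", "o1")):  # cis: right angle at Pd
            d = (dist[a] ** 2 + dist[b] ** 2) ** 0.5
            _set_bound(bm, ix[a], ix[b], 0.85 * d, 1.15 * d)
    DistanceGeometry.DoTriangleSmoothing(bm)
    ps = rdDistGeom.ETKDGv3()
    ps.randomSeed = int(seed)
    ps.useRandomCoords = True
    ps.maxIterations = 200  # fail fast; infeasible bounds cascade to fallbacks
    ps.SetBoundsMat(bm)
    return ps


def restrained_uff_minimize(m, ix, cid, fc=1.0e4, rounds=3, max_its=5000):
    """UFF minimization with the two trans L-Pd-L angles restrained to 180.

    UFF's generic Pd type carries no square-planar d8 preference, so the
    coordination sphere is held planar by restraining C(site)-Pd-O1 and
    X(dg)-Pd-O2 to collinearity; two trans axes through Pd force all five
    atoms into one plane. Restarted up to `rounds` times if unconverged.
    """
    ret = 1
    for _ in range(rounds):
        ff = AllChem.UFFGetMoleculeForceField(m, confId=int(cid))
        ff.UFFAddAngleConstraint(ix["site"], ix["pd"], ix["o1"], False,
                                 178.0, 180.0, fc)
        ff.UFFAddAngleConstraint(ix["dg"], ix["pd"], ix["o2"], False,
                                 178.0, 180.0, fc)
        ret = ff.Minimize(maxIts=max_its)
        if ret == 0:
            break
    return ret, ff.CalcEnergy()


def op_conformers(req):
    mol = get_mol(req["smiles"])
    m, ix = build_pd_complex(mol, int(req["site"]), int(req["dg"]))
    # Prefer square-planar cross bounds; strained rings cannot satisfy them,
    # so probe each bounds stage with a single cheap embedding and fall back
    # (plain Pd-ligand bounds, then stock ETKDG). The restrained minimizer
    # regularizes -- or validation later rejects -- whatever comes out.
    n = int(req["n"])
    seed = int(req["seed"])
    stock = rdDistGeom.ETKDGv3()
    stock.randomSeed = seed
    stock.useRandomCoords = True
    stock.maxIterations = 300
    cids = []
    for ps in (pd_bounds_params(m, ix, seed),
               pd_bounds_params(m, ix, seed, cross=False),
               stock):
        probe = Chem.Mol(m)
        if rdDistGeom.EmbedMolecule(probe, ps) < 0:
            continue
        cids = rdDistGeom.EmbedMultipleConfs(m, n, ps)
        if len(cids):
            break
    # regularize each raw embedding into a square-planar starting geometry
    for c in cids:
        restrained_uff_minimize(m, ix, c)
    out = complex_payload(m, ix)
    out["coords"] = [m.GetConformer(int(c)).GetPositions().tolist()
                     for c in cids]
    out["n_rot_substrate"] = rdMolDescriptors.CalcNumRotatableBonds(mol)
    if len(cids):
        out["molblock"] = Chem.MolToMolBlock(m, confId=int(cids[0]),
                                             kekulize=True)
    return out


def set_conf(m, coords):
    conf = Chem.Conformer(m.GetNumAtoms())
    for i, xyz in enumerate(coords):
        conf.SetAtomPosition(i, tuple(float(v) for v in xyz))
    m.RemoveAllConformers()
    m.AddConformer(conf, assignId=True)


def op_uff(req):
    """UFF optimization / single point of a Pd complex at given coordinates.

    Optimization uses the same square-planar trans-angle restraints as the
    conformer regularization (UFF knows nothing about d8 coordination);
    single points are plain UFF energies.
    """
    mol = get_mol(req["smiles"])
    m, ix = build_pd_complex(mol, int(req["site"]), int(req["dg"]))
    set_conf(m, req["coords"])
    if req.get("optimize", True):
        ret, energy = restrained_uff_minimize(
            m, ix, 0, max_its=int(req.get("max_iter", 5000)))
        converged = ret == 0
    else:
        energy = AllChem.UFFGetMoleculeForceField(m).CalcEnergy()
        converged = True
    return {"energy_kcal": energy,
            "coords": m.GetConformer().GetPositions().tolist(),
            "converged": converged}


def op_molblock(req):
    mol = get_mol(req["smiles"])
    m, ix = build_pd_complex(mol, int(req["site"]), int(req["dg"]))
    set_conf(m, req["coords"])
    return {"molblock": Chem.MolToMolBlock(m, kekulize=True)}


OPS = {
    "parse": op_parse,
    "site_marks": op_site_marks,
    "dg_marks": op_dg_marks,
    "renumber": op_renumber,
    "smarts": op_smarts,
    "ring2d": op_ring2d,
    "strain": op_strain,
    "complex": op_complex,
    "conformers": op_conformers,
    "uff": op_uff,
    "molblock": op_molblock,
}


def main():
    try:
        req = json.load(sys.stdin)
        op = req.get("op")
        if op not in OPS:
            fail("unknown op: " + str(op))
        out = OPS[op](req)
        out["ok"] = True
        json.dump(out, sys.stdout)
        sys.stdout.write("\n")
    except SystemExit:
        raise
    except Exception as e:  # noqa: BLE001
        fail("%s: %s" % (type(e).__name__, e))


if __name__ == "__main__":
    main()
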