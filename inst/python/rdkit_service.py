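"""Line-protocol molecular property service backed by RDKit.

Reads one JSON object per line on stdin, writes one JSON object per line on
stdout.  Request fields:

    molblock : str, optional  -- MDL molblock (preferred input)
    smiles   : str, optional  -- used when no molblock is given
    props    : list of str    -- any of: canonical, qed, logp, sa,
                                 largest_ring, n_rings, formula

Response: {"ok": true, <prop>: <value>, ...} or {"ok": false, "error": msg}.
The process is long-lived; the R side keeps it alive for the whole session so
the RDKit import cost is paid once.
"""
import json
import os
import sys

from rdkit import Chem, RDConfig, rdBase

rdBase.DisableLog("rdApp.*")
sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

from rdkit.Chem import QED, Crippen, rdMolDescriptors  # noqa: E402


def handle(req):
    if "molblock" in req:
        mol = Chem.MolFromMolBlock(req["molblock"])
    elif "smiles" in req:
        mol = Chem.MolFromSmiles(req["smiles"])
    else:
        raise ValueError("request carries neither molblock nor smiles")
    if mol is None:
        raise ValueError("molecule failed to parse/sanitise")
    out = {"ok": True}
    for prop in req.get("props", []):
        if prop == "canonical":
            out[prop] = Chem.MolToSmiles(mol)
        elif prop == "qed":
            out[prop] = QED.qed(mol)
        elif prop == "logp":
            out[prop] = Crippen.MolLogP(mol)
        elif prop == "sa":
            out[prop] = sascorer.calculateScore(mol)
        elif prop == "largest_ring":
            rings = mol.GetRingInfo().AtomRings()
            out[prop] = max((len(r) for r in rings), default=0)
        elif prop == "n_rings":
            out[prop] = rdMolDescriptors.CalcNumRings(mol)
        elif prop == "formula":
            out[prop] = rdMolDescriptors.CalcMolFormula(mol)
        else:
            raise ValueError("unknown property: %s" % prop)
    return out


def main():
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        try:
            out = handle(json.loads(line))
        except Exception as exc:  # noqa: BLE001 - report, never die
            out = {"ok": False, "error": str(exc)}
        sys.stdout.write(json.dumps(out) + "\n")
        sys.stdout.flush()


if __name__ == "__main__":
    main()
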