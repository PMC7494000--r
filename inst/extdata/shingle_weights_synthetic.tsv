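C=O	1.30102999566398
c1ccccc1	1.30102999566398
CC	1.69897000433602
CC(=O)O	1.30102999566398
CC(O)C	1.30102999566398
CC=C	1.30102999566398
CC=CC=C	1.30102999566398
CCN	1.30102999566398
CCO	1.30102999566398
CN	1.30102999566398
CO	1.60205999132796
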