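>vps9_construct_synthetic SYNTHETIC stand-in for UniProt Q96Q42 residues 1513-1657 (anchor residues from cloning primers and reported contacts; interior positions are random draws, NOT the authentic sequence)
KQPDDVTVAPFMATDSLILQMDIEHARTGGEWFHSSDYCSEELVGCMMFDTQVAILGPES
LILRQMMSCVEGSIEAAWDVDGGSTKIRETTDVYYTLLRSELEPKPVLATRDLAPYLDKF
KDVVRNLDLITFGECTEIPQREKLN
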