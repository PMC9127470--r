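>synA1 synthetic ligand family A member 1 (not a real BMP sequence)
CKRHPLYVDFSDVGWNDWIVAPPGYHAFYCHGECPFPLADHLNSTNHAIVQTLVNSVNSK
>synA2 synthetic ligand family A member 2 (not a real BMP sequence)
CKRHPLYVDFSDVGWNDWIVAPPGYQAFYCHGECPFPLADHLNSTNHAIVQTLVNSVNPK
>synB1 synthetic ligand family B member 1 (not a real BMP sequence)
CRRHSLYVDFSDVGWNEWIVAPPGYSAYYCEGECAFPLNSYMNATNHAIVQTLVHFINPE
>synB2 synthetic ligand family B member 2 (not a real BMP sequence)
CRRHALYVDFSDVGWNEWIVAPPGYSAYYCEGECSFPLNAYMNATNHAIVQTLVHFINPD
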