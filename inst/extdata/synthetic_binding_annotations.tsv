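id	chemokine	chemokine_class
SYN001	CCL2	CC
SYN001	CCL3	CC
SYN001	CCL5	CC
SYN002	CCL2	CC
SYN002	CCL8	CC
SYN011	CXCL8	CXC
SYN011	CXCL1	CXC
SYN012	CXCL8	CXC
SYN012	CXCL10	CXC
SYN012	CXCL5	CXC
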