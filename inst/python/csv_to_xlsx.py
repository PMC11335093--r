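"""Convert a CSV table to a single-sheet XLSX workbook (openpyxl)."""
import csv
import sys

from openpyxl import Workbook


def main(csv_path, xlsx_path):
    wb = Workbook()
    ws = wb.active
    ws.title = "phenotype"
    with open(csv_path, newline="") as fh:
        for r, row in enumerate(csv.reader(fh), start=1):
            for c, cell in enumerate(row, start=1):
                if r > 1 and cell != "":
                    try:
                        cell = float(cell)
                    except ValueError:
                        pass
                if cell != "":
                    ws.cell(row=r, column=c, value=cell)
    wb.save(xlsx_path)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
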